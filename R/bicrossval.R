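#' Random 2x2 block partition of a matrix
#'
#' Splits rows and columns at random into two groups each, defining blocks
#' P (rows1 x cols1), Q (rows1 x cols2), R (rows2 x cols1), S (rows2 x cols2).
#' The P-side takes `ceiling(m/2)` rows and `ceiling(n/2)` columns, so each
#' held-out block is predicted from roughly 75% of the data.
#'
#' @param Y matrix with at least 2 rows and 2 columns.
#' @return list of class `bcv_partition`: index vectors `rows1`, `rows2`,
#'   `cols1`, `cols2`.
#' @export
partition_matrix <- function(Y) {
  stop_if_not_matrix(Y, "Y")
  m <- nrow(Y)
  n <- ncol(Y)
  if (m < 2 || n < 2) abort("matrix too small to partition (need >= 2x2)")
  rp <- sample.int(m)
  cp <- sample.int(n)
  m1 <- ceiling(m / 2)
  n1 <- ceiling(n / 2)
  structure(
    list(
      rows1 = sort(rp[seq_len(m1)]), rows2 = sort(rp[-seq_len(m1)]),
      cols1 = sort(cp[seq_len(n1)]), cols2 = sort(cp[-seq_len(n1)])
    ),
    class = "bcv_partition"
  )
}

# rank-k truncated Moore-Penrose pseudoinverse from a precomputed SVD
truncated_pinv <- function(sv, k, tol = 1e-10) {
  k_eff <- min(k, length(sv$d))
  pos <- sv$d[seq_len(k_eff)] > tol * sv$d[1]
  idx <- seq_len(k_eff)[pos]
  if (length(idx) == 0) {
    return(matrix(0, nrow(sv$v), nrow(sv$u)))
  }
  sv$v[, idx, drop = FALSE] %*%
    (t(sv$u[, idx, drop = FALSE]) / sv$d[idx])
}

#' Reconstruct a held-out block from the other three
#'
#' For a matrix split into blocks `[P Q; R S]`, the held-out block P is
#' predicted as `P_k = Q %*% pinv_k(S) %*% R`, where `pinv_k(S)` is the
#' Moore-Penrose pseudoinverse truncated to the k leading singular triplets
#' of S. Exact when the full matrix has rank k and `rank(S) = k`.
#'
#' @param Q,S,R the three observed blocks (`Q`: m1 x n2, `S`: m2 x n2,
#'   `R`: m2 x n1).
#' @param k truncation rank, `1 <= k <= min(dim(S))`.
#' @return the m1 x n1 reconstruction of P.
#' @export
reconstruct_block <- function(Q, S, R, k) {
  if (k < 1 || k > min(dim(S))) {
    abort(sprintf("k = %d outside 1..min(dim(S)) = %d", k, min(dim(S))))
  }
  sv <- svd(S)
  Q %*% truncated_pinv(sv, k) %*% R
}

# one bi-cross-validation pass: reconstruct all four blocks of Y from their
# complementary blocks at every k in k_set; returns list of full-matrix
# reconstructions indexed by k
bcv_reconstruct_all <- function(Y, part, k_set) {
  r1 <- part$rows1; r2 <- part$rows2
  c1 <- part$cols1; c2 <- part$cols2
  P <- Y[r1, c1, drop = FALSE]; Q <- Y[r1, c2, drop = FALSE]
  R <- Y[r2, c1, drop = FALSE]; S <- Y[r2, c2, drop = FALSE]
  svS <- svd(S); svR <- svd(R); svQ <- svd(Q); svP <- svd(P)
  out <- vector("list", length(k_set))
  for (i in seq_along(k_set)) {
    k <- k_set[i]
    Yk <- matrix(NA_real_, nrow(Y), ncol(Y))
    Yk[r1, c1] <- Q %*% truncated_pinv(svS, k) %*% R
    Yk[r1, c2] <- P %*% truncated_pinv(svR, k) %*% S
    Yk[r2, c1] <- S %*% truncated_pinv(svQ, k) %*% P
    Yk[r2, c2] <- R %*% truncated_pinv(svP, k) %*% Q
    out[[i]] <- Yk
  }
  out
}

#' Bi-cross-validation error table over candidate ranks
#'
#' For each of `n_resamples` random partitions, every block of `Y` is
#' reconstructed from the other three at each candidate rank k and the
#' Frobenius norm of the full-matrix reconstruction error is recorded.
#'
#' @param Y probe matrix.
#' @param k_max largest candidate rank; truncated (with a warning) to the
#'   feasible maximum `min(m1, m2, n1, n2)` implied by the split.
#' @param n_resamples number of random partitions (default 250).
#' @param seed optional seed.
#' @return `n_resamples` x `k_eff` matrix of class `bcv_error_table`
#'   (columns named `k1`, `k2`, ...).
#' @export
bcv_error_table <- function(Y, k_max, n_resamples = 250, seed = NULL) {
  stop_if_not_matrix(Y, "Y")
  if (k_max < 1) abort("k_max must be >= 1")
  m <- nrow(Y); n <- ncol(Y)
  feasible <- min(ceiling(m / 2), floor(m / 2), ceiling(n / 2), floor(n / 2))
  if (k_max > feasible) {
    warn(sprintf("k_max truncated from %d to feasible maximum %d", k_max, feasible))
    k_max <- feasible
  }
  k_set <- seq_len(k_max)
  with_seed_opt(seed, {
    errors <- matrix(NA_real_, n_resamples, k_max,
                     dimnames = list(NULL, paste0("k", k_set)))
    for (l in seq_len(n_resamples)) {
      part <- partition_matrix(Y)
      recon <- bcv_reconstruct_all(Y, part, k_set)
      for (i in seq_along(k_set)) errors[l, i] <- frobenius(Y - recon[[i]])
    }
    class(errors) <- c("bcv_error_table", class(errors))
    errors
  })
}

#' Select the number of transcripts from a bi-cross-validation error table
#'
#' Let k* be the rank whose median reconstruction error is smallest. The
#' estimate is the smallest k whose error distribution is not statistically
#' larger than that of k*, judged by a one-sided Wilcoxon rank-sum test
#' (normal approximation with tie correction) at level `alpha`. By
#' construction the estimate never exceeds k*.
#'
#' @param tbl a [bcv_error_table()].
#' @param alpha significance level (default 0.05).
#' @return integer estimate of the number of transcripts.
#' @export
estimate_num_transcripts <- function(tbl, alpha = 0.05) {
  if (nrow(tbl) < 2) abort("need at least 2 resamples")
  meds <- apply(tbl, 2, median)
  if (max(meds) - min(meds) < .Machine$double.eps * max(1, max(meds))) {
    warn("degenerate error table (all candidate ranks equal); returning k = 1")
    return(1L)
  }
  k_star <- which.min(meds)
  for (k in seq_len(k_star)) {
    if (k == k_star) return(as.integer(k_star))
    p <- suppressWarnings(
      wilcox.test(tbl[, k], tbl[, k_star],
                  alternative = "greater", exact = FALSE, correct = TRUE)$p.value
    )
    if (is.na(p) || p >= alpha) return(as.integer(k))
  }
  as.integer(k_star)
}

#' Detect and correct outlier probe intensities by resampling
#'
#' Each random partition yields a cross-validated estimate of every entry of
#' `Y` (each block reconstructed from the other three at the largest usable
#' rank). Over many partitions this gives a per-entry distribution of
#' estimates; an entry farther than `c` robust standard deviations (MAD) from
#' the median of its distribution is declared an outlier and replaced by that
#' median.
#'
#' @param Y probe matrix.
#' @param n_resamples number of partitions (default 250, minimum 10).
#' @param c flag threshold in MAD units (default 3).
#' @param seed optional seed.
#' @return list: `Y_corrected`, `mask` (binary matrix of flagged entries),
#'   `estimate` (per-entry median of cross-validated estimates).
#' @export
detect_and_correct_outliers <- function(Y, n_resamples = 250, c = 3.0, seed = NULL) {
  Y <- validate_probe_matrix(Y)
  if (n_resamples < 10) abort("n_resamples must be >= 10")
  m <- nrow(Y); n <- ncol(Y)
  k_use <- max(1L, min(ceiling(m / 2), floor(m / 2), ceiling(n / 2), floor(n / 2)) - 1L)
  est <- with_seed_opt(seed, {
    acc <- array(NA_real_, c(m, n, n_resamples))
    for (l in seq_len(n_resamples)) {
      part <- partition_matrix(Y)
      acc[, , l] <- bcv_reconstruct_all(Y, part, k_use)[[1]]
    }
    acc
  })
  med <- apply(est, c(1, 2), median)
  madv <- apply(est, c(1, 2), mad)
  # guard: on (near-)noiseless data estimates coincide with Y and MAD is 0;
  # a floor keeps numerical dust from being flagged
  floor_tol <- 1e-8 * (abs(med) + 1e-8)
  mask <- (abs(Y - med) > c * pmax(madv, floor_tol)) * 1
  dimnames(mask) <- dimnames(Y)
  dimnames(med) <- dimnames(Y)
  Y_corrected <- Y
  Y_corrected[mask == 1] <- pmax(med[mask == 1], 0)
  if (any(rowSums(mask) == n)) {
    warn("at least one probe had every sample flagged as an outlier")
  }
  list(Y_corrected = Y_corrected, mask = mask, estimate = med)
}

#' One-call transcript-number estimation for a raw probe matrix
#'
#' Convenience wrapper running the rank-estimation pipeline: homoscedastic
#' rescale, outlier correction, bi-cross-validation error table, Wilcoxon
#' selection.
#'
#' @param Y raw probe matrix.
#' @param k_max largest candidate rank (default 6).
#' @param n_resamples partitions for both outlier correction and the error
#'   table (default 250).
#' @param alpha Wilcoxon level.
#' @param power rescale exponent.
#' @param outlier logical; run outlier correction first (default TRUE).
#' @param seed optional seed.
#' @return integer transcript-number estimate with the error table attached
#'   as attribute `table`.
#' @export
estimate_transcript_number <- function(Y, k_max = 6, n_resamples = 250,
                                       alpha = 0.05, power = 0.7,
                                       outlier = TRUE, seed = NULL) {
  Y <- drop_dead_probes(Y)
  rs <- homoscedastic_rescale(Y, power)
  Ys <- rs$Y_scaled
  with_seed_opt(seed, {
    if (outlier) {
      Ys <- detect_and_correct_outliers(Ys, n_resamples = n_resamples)$Y_corrected
    }
    tbl <- bcv_error_table(Ys, k_max = k_max, n_resamples = n_resamples)
    k_hat <- estimate_num_transcripts(tbl, alpha = alpha)
    attr(k_hat, "table") <- tbl
    k_hat
  })
}
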