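#' Evaluate the robust column-similarity objective for a diagonal scaling
#'
#' The objective is the summed absolute log-difference between scaled columns
#' of `W` over column pairs and informative probe rows:
#' `sum_i sum_{j<k} |log(d_j W_ij) - log(d_k W_ik)|`. A row is informative
#' for a pair when both entries exceed `row_floor` times that row's maximum:
#' in the affinity-times-binary-structure model a structural zero is tiny
#' relative to its own row's maximum (the probe affinity), whatever the
#' probe's affinity magnitude, so row-relative masking separates the
#' scale-carrying "shared" entries from the zeros whose log carries no
#' information. Used by tests as a brute-force oracle target and exported
#' for diagnostics.
#'
#' @param W non-negative probes x k matrix.
#' @param d positive diagonal scaling, length k.
#' @param row_floor mask threshold relative to each row's maximum.
#' @return the objective value.
#' @export
scaling_objective <- function(W, d, row_floor = 0.1) {
  k <- ncol(W)
  if (length(d) != k || any(d <= 0)) abort("d must be positive with one entry per column")
  keep <- W > row_floor * apply(W, 1, max)
  lw <- suppressWarnings(log(W))
  x <- log(d)
  total <- 0
  for (j in seq_len(k - 1)) {
    for (kk in (j + 1):k) {
      rows <- keep[, j] & keep[, kk]
      if (any(rows)) {
        total <- total + sum(abs((x[j] + lw[rows, j]) - (x[kk] + lw[rows, kk])))
      }
    }
  }
  total
}

#' Solve the diagonal gauge-fixing problem (Adapt scaling)
#'
#' NMF is unique only up to `(W D) (D^-1 H)` for positive diagonal `D`. In
#' the affinity-times-binary-structure model the non-zero entries of every
#' row of `A G` equal the probe affinity, so in the correct gauge the
#' columns of `W D` agree on every probe shared by two transcripts. The L1
#' objective (see [scaling_objective()]) is minimized in `x = log(d)`:
#' pairwise offsets are estimated robustly as
#' `x_j - x_k = median_i(log W_ik - log W_ij)` over the informative rows of
#' the pair (both entries above `row_floor` of their row maximum), then
#' reconciled by weighted least squares over the pair graph, and finally
#' refined by exact coordinate-descent medians on the masked L1 objective.
#' The objective is invariant to a common shift of all `x_j`; the gauge is
#' `x_1 = 0` (`d[1] = 1`).
#'
#' @param W non-negative probes x k matrix; every column must contain a
#'   positive entry.
#' @param row_floor mask threshold relative to each row's maximum.
#' @return positive vector `d` of length k with `d[1] = 1`; the achieved
#'   objective is attached as attribute `objective`.
#' @export
solve_scaling <- function(W, row_floor = 0.1) {
  stop_if_not_matrix(W, "W")
  if (any(W < 0)) abort("W must be non-negative")
  k <- ncol(W)
  colmax <- apply(W, 2, max)
  if (any(colmax <= 0)) {
    abort(sprintf("column(s) %s carry no scale information (all entries ~ 0)",
                  paste(which(colmax <= 0), collapse = ", ")))
  }
  if (k == 1) {
    d <- 1
    attr(d, "objective") <- 0
    return(d)
  }
  keep <- W > row_floor * apply(W, 1, max)
  if (any(colSums(keep) == 0)) {
    warn("a column of W dominates no probe; its scale is weakly determined")
  }
  lw <- suppressWarnings(log(W))
  pairs <- utils::combn(k, 2)
  D <- matrix(0, ncol(pairs), k)
  rhs <- numeric(ncol(pairs))
  wts <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    j <- pairs[1, p]; kk <- pairs[2, p]
    rows <- keep[, j] & keep[, kk]
    D[p, j] <- 1; D[p, kk] <- -1
    if (sum(rows) >= 2) {
      rhs[p] <- median(lw[rows, kk] - lw[rows, j])
      wts[p] <- sum(rows)
    }
  }
  use <- wts > 0
  if (!any(use)) {
    warn("no column pair shares informative probes; returning the identity scaling")
    d <- rep(1, k)
    names(d) <- colnames(W)
    attr(d, "objective") <- scaling_objective(W, d, row_floor)
    return(d)
  }
  sw <- sqrt(wts[use])
  Df <- D[use, -1, drop = FALSE] * sw # gauge x_1 = 0
  x <- c(0, as.numeric(MASS::ginv(crossprod(Df)) %*% crossprod(Df, rhs[use] * sw)))
  # exact coordinate descent on the masked L1 objective: the optimal x_j given
  # the others is the median of (x_k + lw_ik) - lw_ij over informative rows
  for (sweep_i in seq_len(100)) {
    delta <- 0
    for (j in seq_len(k)) {
      targets <- c()
      for (kk in setdiff(seq_len(k), j)) {
        rows <- keep[, j] & keep[, kk]
        if (any(rows)) targets <- c(targets, x[kk] + lw[rows, kk] - lw[rows, j])
      }
      if (length(targets) == 0) next
      x_new <- median(targets)
      delta <- max(delta, abs(x_new - x[j]))
      x[j] <- x_new
    }
    if (delta < 1e-12) break
  }
  # coordinate descent can stall on a non-optimal vertex of the piecewise
  # linear objective; a shrinking pattern search finishes the job
  obj_at <- function(x) scaling_objective(W, exp(x - x[1]), row_floor)
  f_cur <- obj_at(x)
  for (step in c(0.2, 0.05, 0.01, 0.002)) {
    repeat {
      improved <- FALSE
      for (j in 2:k) {
        for (s in c(step, -step)) {
          x_try <- x
          x_try[j] <- x_try[j] + s
          f_try <- obj_at(x_try)
          if (f_try < f_cur - 1e-12) {
            x <- x_try
            f_cur <- f_try
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  }
  x <- x - x[1]
  d <- exp(x)
  names(d) <- colnames(W)
  attr(d, "objective") <- scaling_objective(W, d, row_floor)
  d
}

#' Apply a diagonal scaling to an NMF factor pair
#'
#' `(W, H) -> (W D, D^-1 H)`; the product, and therefore the reconstruction
#' of the data, is unchanged.
#'
#' @param W,H non-negative factors with matching inner dimension.
#' @param d positive diagonal entries.
#' @return list: `W_tilde`, `H_tilde`.
#' @export
apply_scaling <- function(W, H, d) {
  if (any(d <= 0) || any(!is.finite(d))) abort("diagonal entries must be positive and finite")
  if (length(d) != ncol(W) || length(d) != nrow(H)) abort("length(d) must match the inner dimension")
  list(W_tilde = sweep(W, 2, d, "*"), H_tilde = sweep(H, 1, d, "/"))
}

#' Extract per-probe affinities from the scaled structure factor
#'
#' In the gauge-fixed factor `W_tilde ~ A G` with binary `G`, the non-zero
#' entries of each row all equal that probe's affinity, so the affinity is
#' the row maximum.
#'
#' @param W_tilde non-negative probes x k matrix with no all-zero row.
#' @return positive affinity vector, one entry per probe.
#' @export
extract_affinities <- function(W_tilde) {
  stop_if_not_matrix(W_tilde, "W_tilde")
  a <- apply(W_tilde, 1, max)
  if (any(a <= 0)) {
    bad <- rownames(W_tilde)[a <= 0] %||% which(a <= 0)
    abort(sprintf(
      "probe(s) %s hybridize against no transcript (all-zero row in W_tilde)",
      paste(bad, collapse = ", ")
    ))
  }
  a
}

#' Continuous structure estimate from the scaled factor
#'
#' `G_tilde = diag(A)^-1 W_tilde`: each row of the scaled structure factor is
#' divided by its affinity (its own maximum), so every entry lies in `[0, 1]`
#' and each row attains 1 at its largest entry.
#'
#' @param W_tilde scaled structure factor.
#' @param a affinity vector (defaults to [extract_affinities()] of `W_tilde`).
#' @return probes x k matrix with entries in `[0, 1]`.
#' @export
continuous_structure <- function(W_tilde, a = extract_affinities(W_tilde)) {
  if (any(a <= 0)) abort("affinities must be positive")
  G_tilde <- W_tilde / a
  G_tilde
}

#' Raise near-zero structure entries to a floor
#'
#' Log-domain operations downstream are undefined at zero; entries of the
#' continuous structure below `floor` are clamped up to it ("filled"
#' structure).
#'
#' @param G_tilde continuous structure.
#' @param floor clamp value (default 1e-3).
#' @return matrix with `min(result) >= floor`, same shape and order.
#' @export
fill_structure <- function(G_tilde, floor = 1e-3) {
  pmax(G_tilde, floor)
}

#' Estimate concentrations when the gene structure is known
#'
#' Wang-model deconvolution: solves `Y ~ diag(A) G T` for non-negative `T`
#' by per-sample non-negative least squares. When `A` is not supplied it is
#' estimated by alternating between NNLS for `T` and a closed-form
#' per-probe affinity update, initialized from the leading left singular
#' vector of `Y` (the single-isoform summarization affinity).
#'
#' Some structures are non-identifiable: if the columns of `G` are linearly
#' dependent (e.g. a full isoform plus two complementary cassette isoforms),
#' different concentration matrices reproduce the same probe intensities.
#' This is detected by a column-rank check and reported via the
#' `identifiable` attribute.
#'
#' @param Y probe matrix.
#' @param G binary structure, probes x transcripts.
#' @param A optional affinity vector.
#' @return transcripts x samples concentration matrix; attributes
#'   `residual` (Frobenius residual of the fit), `identifiable` (logical),
#'   `A` (affinities used).
#' @export
deconvolve_known_structure <- function(Y, G, A = NULL) {
  Y <- validate_probe_matrix(Y)
  G <- validate_structure(G)
  if (nrow(G) != nrow(Y)) abort("G and Y must have the same probes")
  k <- ncol(G)
  identifiable <- qr(G)$rank == k
  solve_T <- function(X) {
    T_hat <- matrix(0, k, ncol(Y))
    for (s in seq_len(ncol(Y))) T_hat[, s] <- nnls_solve(X, Y[, s])
    T_hat
  }
  if (is.null(A)) {
    sv <- svd(Y, nu = 1, nv = 0)
    A <- abs(sv$u[, 1])
    A[A < 1e-8] <- 1e-8
    A <- A * sqrt(mean(Y)) / mean(A)
    for (it in seq_len(25)) {
      T_hat <- solve_T(A * G)
      Z <- G %*% T_hat
      num <- rowSums(Y * Z)
      den <- rowSums(Z * Z)
      A_new <- ifelse(den > 0, pmax(num / den, 1e-8), A)
      if (max(abs(A_new - A)) < 1e-9 * max(A)) {
        A <- A_new
        break
      }
      A <- A_new
    }
  }
  if (length(A) != nrow(Y)) abort("length(A) must equal nrow(Y)")
  T_hat <- solve_T(A * G)
  rownames(T_hat) <- colnames(G)
  colnames(T_hat) <- colnames(Y)
  attr(T_hat, "residual") <- frobenius(Y - (A * G) %*% T_hat)
  attr(T_hat, "identifiable") <- identifiable
  attr(T_hat, "A") <- A
  if (!identifiable) {
    warn("gene structure is non-identifiable: concentrations are one of several exact solutions")
  }
  T_hat
}
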