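#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative probe matrix as `Y ~ W %*% H` with `W >= 0`
#' (probes x k, structure side) and `H >= 0` (k x samples, concentration
#' side) by Lee-Seung multiplicative updates for the Frobenius objective.
#' The loss is non-increasing across iterations; the default budget of 3000
#' iterations is ample for convergence at these problem sizes.
#'
#' @param Y non-negative matrix, probes x samples.
#' @param k internal dimension, `1 <= k <= min(dim(Y))`.
#' @param n_iter iterations per restart (default 3000).
#' @param n_restarts random restarts; the lowest-loss fit is returned.
#' @param tol optional relative-loss early-stopping tolerance (0 disables,
#'   the default: a fixed budget keeps runs comparable).
#' @param seed optional seed.
#' @return list of class `nmf_fit`: `W`, `H`, `loss`, `loss_trace`
#'   (per-iteration losses of the winning restart), `k`, `seed`.
#' @export
nmf_factorize <- function(Y, k, n_iter = 3000, n_restarts = 1, tol = 0,
                          seed = NULL) {
  stop_if_not_matrix(Y, "Y")
  if (any(Y < 0)) abort("Y must be non-negative")
  m <- nrow(Y); n <- ncol(Y)
  if (k < 1 || k > min(m, n)) abort(sprintf("k = %d outside 1..min(dim(Y)) = %d", k, min(m, n)))
  eps <- 1e-12
  init_scale <- sqrt(mean(Y) / k)
  with_seed_opt(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      W <- matrix(runif(m * k), m, k) * init_scale
      H <- matrix(runif(k * n), k, n) * init_scale
      trace <- numeric(n_iter)
      for (it in seq_len(n_iter)) {
        H <- H * (crossprod(W, Y)) / (crossprod(W, W %*% H) + eps)
        W <- W * (Y %*% t(H)) / (W %*% tcrossprod(H) + eps)
        trace[it] <- frobenius(Y - W %*% H)
        if (!is.finite(trace[it])) abort(sprintf(
          "NMF loss became non-finite at iteration %d (k = %d, restart %d)", it, k, r
        ))
        if (tol > 0 && it > 1 &&
            (trace[it - 1] - trace[it]) < tol * max(trace[it - 1], eps)) {
          trace <- trace[seq_len(it)]
          break
        }
      }
      loss <- trace[length(trace)]
      if (is.null(best) || loss < best$loss) {
        best <- list(W = W, H = H, loss = loss, loss_trace = trace)
      }
    }
    rownames(best$W) <- rownames(Y)
    colnames(best$W) <- paste0("tr_", seq_len(k))
    rownames(best$H) <- paste0("tr_", seq_len(k))
    colnames(best$H) <- colnames(Y)
    structure(c(best, list(k = as.integer(k), seed = seed)), class = "nmf_fit")
  })
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf(
    "<nmf_fit> %d x %d at k = %d, Frobenius loss %.4g after %d iteration(s)\n",
    nrow(x$W), ncol(x$H), x$k, x$loss, length(x$loss_trace)
  ))
  invisible(x)
}
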