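#' @importFrom stats median mad rnorm runif sd wilcox.test coef
#' @importFrom utils head read.delim write.table
#' @importFrom rlang abort warn .data
NULL

frobenius <- function(X) sqrt(sum(X^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

# run `expr` under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL uses the current stream
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# derive a per-unit seed from a master seed, kept inside 32-bit range
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 + 104729 * as.double(i)) %% 2147483647L) + 1L
}

stop_if_not_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("%s must be a numeric matrix", what))
  }
}

# Lawson-Hanson non-negative least squares: min ||A x - b||_2 s.t. x >= 0.
# Problems here have <= 8 unknowns, so the active-set loop is cheap.
nnls_solve <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol * max(1, max(abs(w))))) {
    iter <- iter + 1L
    if (iter > 30L * n) break
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- qr.coef(qr(Ap), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) {
        x <- z
        break
      }
      neg <- passive & (z <= tol)
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  as.numeric(x)
}
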