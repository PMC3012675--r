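#' Homoscedastic rescaling of probe intensities
#'
#' Least-squares factorization assumes homoscedastic residuals, but residual
#' magnitude grows with probe affinity. Dividing every probe's intensities by
#' the median of that probe across all samples raised to the power 0.7 brings
#' the residuals much closer to constant variance. The exponent 0.7 was
#' calibrated on single-transcript genes; it is exposed but rarely worth
#' changing.
#'
#' @param Y probe matrix (non-negative, rows with positive medians).
#' @param power exponent applied to the per-probe median (default 0.7).
#' @return list: `Y_scaled` and `scale` (per-probe divisor, for undoing).
#' @export
homoscedastic_rescale <- function(Y, power = 0.7) {
  Y <- validate_probe_matrix(Y)
  med <- apply(Y, 1, median)
  if (any(med <= 0)) {
    abort(sprintf(
      "probe(s) with non-positive median intensity cannot be rescaled: %s",
      paste(rownames(Y)[med <= 0], collapse = ", ")
    ))
  }
  scale <- med^power
  list(Y_scaled = Y / scale, scale = scale)
}

#' Drop probes with non-positive median intensity
#'
#' A probe whose median across samples is not positive (dead probe, or more
#' than half of its values clipped at zero) cannot be rescaled and carries
#' almost no signal; pipeline wrappers remove such probes with a warning
#' before the homoscedastic rescale.
#'
#' @param Y probe matrix.
#' @return `Y` without the dead probe rows; errors if fewer than 2 remain.
#' @export
drop_dead_probes <- function(Y) {
  med <- apply(Y, 1, median)
  dead <- med <= 0
  if (any(dead)) {
    warn(sprintf("dropping %d dead probe(s) with non-positive median: %s",
                 sum(dead), paste(head(rownames(Y)[dead], 5), collapse = ", ")))
    Y <- Y[!dead, , drop = FALSE]
    if (nrow(Y) < 2) abort("fewer than 2 usable probes after dropping dead probes")
  }
  Y
}

#' Undo a per-probe rescale
#'
#' @param X matrix whose rows were divided by `scale`.
#' @param scale per-row positive divisors as returned by
#'   [homoscedastic_rescale()].
#' @return the matrix on the original intensity scale.
#' @export
undo_rescale <- function(X, scale) {
  stop_if_not_matrix(X, "X")
  if (length(scale) != nrow(X)) abort("scale length must equal nrow(X)")
  X * scale
}
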