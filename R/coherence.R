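#' Force a shared hybridization pattern within each probeset
#'
#' Probes of one probeset interrogate the same exon (or exon part), so a real
#' isoform contains either all of them or none: the corresponding rows of the
#' structure matrix must be identical. For each probeset the closest rank-one
#' block is obtained from the column means of that probeset's rows; with
#' `round = TRUE` (the published correction) the means are rounded to binary
#' (ties at exactly 0.5 round up), with `round = FALSE` the continuous means
#' are kept — useful when a threshold sweep follows.
#'
#' Caveat: a genuine splicing event that splits a probeset (e.g. a novel
#' donor site inside an exon) is erased by this correction; disable it when
#' hunting for sub-probeset events.
#'
#' @param G_tilde continuous structure, probes x transcripts.
#' @param probeset character/factor vector assigning each row to a probeset.
#' @param round round the block means to binary (default TRUE).
#' @return matrix of the same shape; within each probeset all rows identical.
#' @export
enforce_probeset_coherence <- function(G_tilde, probeset, round = TRUE) {
  stop_if_not_matrix(G_tilde, "G_tilde")
  if (length(probeset) != nrow(G_tilde)) {
    abort("probeset assignment must cover every probe exactly once")
  }
  if (any(is.na(probeset) | probeset == "")) abort("unassigned probe (empty probeset id)")
  out <- G_tilde
  for (ps in unique(probeset)) {
    rows <- which(probeset == ps)
    mu <- colMeans(G_tilde[rows, , drop = FALSE])
    if (round) mu <- as.numeric(mu >= 0.5)
    out[rows, ] <- matrix(mu, length(rows), ncol(G_tilde), byrow = TRUE)
  }
  out
}

#' Binarize a continuous structure at a threshold
#'
#' Entries strictly above `th` become 1. The default 0.5 is the threshold
#' minimizing the overall Hamming error in simulation. Transcript columns
#' left with no probe are dropped with a warning (the transcript is
#' unsupported at this threshold).
#'
#' @param G_tilde continuous structure.
#' @param th threshold in (0, 1).
#' @return binary matrix, possibly with fewer columns.
#' @export
threshold_structure <- function(G_tilde, th = 0.5) {
  if (th <= 0 || th >= 1) abort("th must lie in (0, 1)")
  G <- (G_tilde > th) * 1
  empty <- colSums(G) == 0
  if (any(empty)) {
    warn(sprintf("dropping %d transcript column(s) unsupported at threshold %.2f",
                 sum(empty), th))
    G <- G[, !empty, drop = FALSE]
  }
  G
}

#' Read transcript concentrations off the concentration-side factor
#'
#' After gauge fixing, the concentration factor is identified with the
#' transcript concentration matrix. Rows are labelled to match the structure
#' columns; values are relative abundances on an arbitrary common scale.
#'
#' @param H_tilde non-negative k x samples factor.
#' @param G structure matrix whose columns define transcript order.
#' @return transcripts x samples concentration matrix.
#' @export
estimate_concentrations <- function(H_tilde, G) {
  stop_if_not_matrix(H_tilde, "H_tilde")
  if (nrow(H_tilde) != ncol(G)) {
    abort("row count of concentrations must equal transcript count of the structure")
  }
  T_hat <- H_tilde
  rownames(T_hat) <- colnames(G)
  T_hat
}
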