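#' Validate a probe-by-sample intensity matrix
#'
#' A probe matrix holds background-removed, normalized intensities for the
#' probes of one gene (rows) across samples (columns). All entries must be
#' finite and non-negative and both dimensions at least 2.
#'
#' @param Y numeric matrix, probes x samples; rownames are probe ids,
#'   colnames sample ids (assigned if missing).
#' @return the validated matrix with row/column names guaranteed.
#' @export
validate_probe_matrix <- function(Y) {
  stop_if_not_matrix(Y, "Y")
  if (nrow(Y) < 2 || ncol(Y) < 2) {
    abort("probe matrix needs at least 2 probes and 2 samples")
  }
  if (any(!is.finite(Y))) abort("probe matrix contains non-finite entries")
  if (any(Y < 0)) abort("probe matrix contains negative entries")
  if (is.null(rownames(Y))) rownames(Y) <- paste0("probe_", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("sample_", seq_len(ncol(Y)))
  Y
}

#' Validate a binary gene-structure matrix
#'
#' The structure matrix G is binary, probes x transcripts: entry (i, j) is 1
#' when probe i hybridizes against transcript j. Every probe must hybridize
#' against at least one transcript and every transcript must carry at least
#' one probe.
#'
#' @param G numeric 0/1 matrix, probes x transcripts.
#' @return the validated matrix.
#' @export
validate_structure <- function(G) {
  stop_if_not_matrix(G, "G")
  if (!all(G %in% c(0, 1))) abort("structure matrix must be binary (0/1)")
  if (any(rowSums(G) == 0)) {
    abort(sprintf(
      "probe(s) %s hybridize against no transcript",
      paste(head(which(rowSums(G) == 0), 5), collapse = ", ")
    ))
  }
  if (any(colSums(G) == 0)) abort("structure matrix has an all-zero transcript column")
  G
}

#' Bundle and cross-check a probe matrix with its annotation
#'
#' Checks that every probe in `Y` appears exactly once in the annotation and
#' materializes the probeset partition in the row order of `Y`.
#'
#' @param Y probe matrix (see [validate_probe_matrix()]).
#' @param annotation data frame with at least `probe_id`, `probeset_id`,
#'   `gene_id` columns; optional `exon_label`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @return a list of class `gene_bundle`: `Y`, `annotation` (row-aligned to
#'   `Y`), `probeset` (character vector aligned to rows of `Y`), `gene_id`.
#' @export
validate_gene_inputs <- function(Y, annotation) {
  Y <- validate_probe_matrix(Y)
  required <- c("probe_id", "probeset_id", "gene_id")
  missing_cols <- setdiff(required, names(annotation))
  if (length(missing_cols) > 0) {
    abort(sprintf("annotation lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  dup <- annotation$probe_id[duplicated(annotation$probe_id)]
  if (length(dup) > 0) {
    abort(sprintf("annotation has duplicated probe_id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  absent <- setdiff(rownames(Y), annotation$probe_id)
  if (length(absent) > 0) {
    abort(sprintf("probe(s) in matrix missing from annotation: %s", paste(absent, collapse = ", ")))
  }
  ann <- annotation[match(rownames(Y), annotation$probe_id), , drop = FALSE]
  if (length(unique(ann$gene_id)) > 1) {
    abort("annotation covers more than one gene")
  }
  probeset <- as.character(ann$probeset_id)
  if (any(is.na(probeset) | probeset == "")) abort("empty probeset_id in annotation")
  structure(
    list(
      Y = Y,
      annotation = tibble::as_tibble(ann),
      probeset = probeset,
      gene_id = ann$gene_id[1]
    ),
    class = "gene_bundle"
  )
}

#' @export
print.gene_bundle <- function(x, ...) {
  cat(sprintf(
    "<gene_bundle> gene %s: %d probes x %d samples, %d probesets\n",
    x$gene_id, nrow(x$Y), ncol(x$Y), length(unique(x$probeset))
  ))
  invisible(x)
}

pad_columns <- function(M, k) {
  if (ncol(M) >= k) return(M)
  pad <- matrix(0, nrow(M), k - ncol(M))
  colnames(pad) <- paste0(".pad_", seq_len(ncol(pad)))
  cbind(M, pad)
}

#' Match predicted transcript columns to a reference structure
#'
#' Transcript order out of a factorization is arbitrary, so before any
#' comparison the predicted columns are resorted to be as similar as possible
#' to the reference. The cost of assigning predicted column q to reference
#' column r is their L1 distance (Hamming distance on binary input); the
#' permutation minimizing the total cost is found by exhaustive optimal
#' assignment (column counts are capped at 8, comfortably above the model's
#' practical limit of ~6 transcripts). When column counts differ the smaller
#' matrix is padded with all-zero columns; indices pointing at padded
#' predicted columns are reported in the `unmatched` attribute.
#'
#' @param G_hat predicted structure (binary or continuous), probes x k_hat.
#' @param G_ref reference binary structure, probes x k_ref.
#' @return integer vector `perm` of length `max(k_hat, k_ref)`: `perm[j]` is
#'   the (padded) predicted column assigned to reference column j. Apply as
#'   `G_hat[, perm]` and `T_hat[perm, ]` after padding. Ties are broken
#'   toward the lexicographically smallest permutation.
#' @export
match_transcript_columns <- function(G_hat, G_ref) {
  stop_if_not_matrix(G_hat, "G_hat")
  stop_if_not_matrix(G_ref, "G_ref")
  if (nrow(G_hat) != nrow(G_ref)) abort("probe counts differ between structures")
  k <- max(ncol(G_hat), ncol(G_ref))
  if (k > 8) abort("assignment supported for at most 8 transcript columns")
  n_hat <- ncol(G_hat)
  Gh <- pad_columns(G_hat, k)
  Gr <- pad_columns(G_ref, k)
  # cost[q, r] = L1 distance between predicted column q and reference column r
  cost <- matrix(0, k, k)
  for (q in seq_len(k)) {
    for (r in seq_len(k)) cost[q, r] <- sum(abs(Gh[, q] - Gr[, r]))
  }
  perms <- all_permutations(k)
  totals <- vapply(seq_len(nrow(perms)), function(i) {
    sum(cost[cbind(perms[i, ], seq_len(k))])
  }, numeric(1))
  best <- perms[which.min(totals), ] # rows are in lexicographic order
  attr(best, "unmatched") <- which(best > n_hat)
  attr(best, "total_cost") <- min(totals)
  best
}

# all permutations of 1..k, rows in lexicographic order
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}
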