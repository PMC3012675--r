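#' Read a probe-by-sample intensity matrix from TSV
#'
#' Expected layout: header row of sample ids, first column of probe ids,
#' numeric cells. Negative, missing or non-numeric cells are errors naming
#' the offending cell.
#'
#' @param path TSV file.
#' @return validated numeric matrix with probe rownames and sample colnames.
#' @export
read_probe_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0) abort(sprintf("empty matrix file: %s", path))
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0 || ncol(df) < 2) abort(sprintf("empty or id-only matrix file: %s", path))
  ids <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-numeric cell at probe '%s', sample '%s'",
      ids[bad[1, 1]], colnames(cells)[bad[1, 2]]
    ))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)
    abort(sprintf(
      "negative intensity at probe '%s', sample '%s'",
      ids[bad[1, 1]], colnames(cells)[bad[1, 2]]
    ))
  }
  dimnames(num) <- list(ids, colnames(cells))
  validate_probe_matrix(num)
}

#' Write a matrix as TSV with an id column
#'
#' @param X matrix with rownames.
#' @param path output file.
#' @param id_col name of the first (id) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(X, path, id_col = "probe_id") {
  # %.17g round-trips doubles exactly through text
  cells <- matrix(sprintf("%.17g", X), nrow(X))
  lines <- c(
    paste(c(id_col, colnames(X) %||% paste0("col_", seq_len(ncol(X)))),
          collapse = "\t"),
    vapply(seq_len(nrow(X)), function(i) {
      paste(c((rownames(X) %||% as.character(seq_len(nrow(X))))[i], cells[i, ]),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe annotation table from TSV
#'
#' Required columns: `probe_id`, `probeset_id`, `gene_id`; optional
#' `exon_label`, `chrom`, `start`, `end`, `strand` (1-based inclusive).
#'
#' @param path TSV file with a header row.
#' @return tibble.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- tibble::as_tibble(read.delim(path, check.names = FALSE))
  required <- c("probe_id", "probeset_id", "gene_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("annotation lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df$probe_id <- as.character(df$probe_id)
  df$probeset_id <- as.character(df$probeset_id)
  df
}

#' Write a fitted gene to a directory
#'
#' Emits `G.tsv` (binary structure), `Gtilde.tsv` (continuous structure),
#' `T.tsv` (concentrations), `affinities.tsv`, `report.json` (transcript
#' number, loss, outlier count, timings, seed) and, when the annotation
#' carries genomic coordinates, `transcripts.bed` (0-based half-open,
#' converted from the 1-based annotation; one line per included probe per
#' transcript).
#'
#' @param fit a `gene_fit` from [run_gene()].
#' @param dir output directory (created if needed).
#' @param annotation optional annotation with `chrom`, `start`, `end` for the
#'   BED output.
#' @return the directory, invisibly.
#' @export
write_gene_result <- function(fit, dir, annotation = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix_tsv(fit$G, file.path(dir, "G.tsv"))
  write_matrix_tsv(fit$G_tilde, file.path(dir, "Gtilde.tsv"))
  write_matrix_tsv(fit$T, file.path(dir, "T.tsv"), id_col = "transcript_id")
  write_matrix_tsv(cbind(affinity = fit$A), file.path(dir, "affinities.tsv"))
  report <- list(
    gene_id = fit$gene_id,
    k = fit$k,
    k_estimated = fit$k_estimated,
    loss = fit$loss,
    n_outliers = sum(fit$outlier_mask),
    seed = fit$config$seed,
    improvements = fit$config$improvements,
    threshold = fit$config$th,
    timings = as.list(fit$timings)
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  has_coords <- !is.null(annotation) &&
    all(c("chrom", "start", "end") %in% names(annotation))
  if (has_coords) {
    ann <- annotation[match(rownames(fit$G), annotation$probe_id), , drop = FALSE]
    lines <- character(0)
    for (j in seq_len(ncol(fit$G))) {
      inc <- which(fit$G[, j] == 1)
      if (length(inc) == 0) next
      lines <- c(lines, sprintf(
        "%s\t%d\t%d\t%s\t0\t%s",
        ann$chrom[inc], ann$start[inc] - 1L, ann$end[inc],
        colnames(fit$G)[j] %||% paste0("tr_", j),
        if ("strand" %in% names(ann)) ann$strand[inc] else "."
      ))
    }
    writeLines(lines, file.path(dir, "transcripts.bed"))
  }
  invisible(dir)
}

#' Check a gene report against the shipped schema
#'
#' Verifies field presence and types for `report.json` files written by
#' [write_gene_result()] (the schema itself ships in
#' `inst/extdata/report-schema.json`).
#'
#' @param path path to a `report.json`.
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validate_report <- function(path) {
  rep <- jsonlite::read_json(path)
  schema <- jsonlite::read_json(
    system.file("extdata", "report-schema.json", package = "isodeconv")
  )
  for (field in names(schema$properties)) {
    if (field %in% schema$required && is.null(rep[[field]])) {
      abort(sprintf("report lacks required field '%s'", field))
    }
    type <- schema$properties[[field]]$type
    if (!is.null(rep[[field]])) {
      ok <- switch(type,
        integer = is.numeric(rep[[field]]),
        number = is.numeric(rep[[field]]),
        string = is.character(rep[[field]]),
        boolean = is.logical(rep[[field]]),
        object = is.list(rep[[field]]),
        TRUE
      )
      if (!ok) abort(sprintf("report field '%s' is not of type %s", field, type))
    }
  }
  invisible(TRUE)
}

#' Write a synthetic dataset to disk
#'
#' Per gene: `Y.tsv`, truth `G.tsv`, `T.tsv`, `A.tsv` and `annotation.tsv`;
#' plus a dataset-level `manifest.json` with configuration and per-gene
#' seeds. Writing is deterministic: the same dataset yields byte-identical
#' files.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in dataset$genes) {
    gdir <- file.path(dir, g$gene_id)
    dir.create(gdir, showWarnings = FALSE)
    write_matrix_tsv(g$Y, file.path(gdir, "Y.tsv"))
    write_matrix_tsv(g$G, file.path(gdir, "G.tsv"))
    write_matrix_tsv(g$T, file.path(gdir, "T.tsv"), id_col = "transcript_id")
    write_matrix_tsv(cbind(affinity = g$A), file.path(gdir, "A.tsv"))
    write.table(g$annotation, file.path(gdir, "annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    config = unclass(dataset$config),
    genes = lapply(seq_len(nrow(dataset$manifest)), function(i) {
      as.list(dataset$manifest[i, ])
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
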