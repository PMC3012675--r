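#' Entrywise confusion counts between binary structures
#'
#' Compares a predicted binary structure with the truth over all
#' probe x transcript cells. Columns must already be matched (see
#' [match_transcript_columns()]): TP cells are 1 in both, TN 0 in both, FP
#' predicted 1 but truly 0, FN predicted 0 but truly 1.
#'
#' @param G_true,G_pred binary matrices of identical shape.
#' @return named numeric vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(G_true, G_pred) {
  if (!all(dim(G_true) == dim(G_pred))) abort("shape mismatch after matching")
  c(
    TP = sum(G_true == 1 & G_pred == 1),
    TN = sum(G_true == 0 & G_pred == 0),
    FP = sum(G_true == 0 & G_pred == 1),
    FN = sum(G_true == 1 & G_pred == 0)
  )
}

#' Structure-recovery metrics from confusion counts
#'
#' Hamming distance error rate `HD = (FP + FN) / N` (fraction of wrong
#' cells), sensitivity `SN = TP / (TP + FN)` (truly hybridizing cells
#' recovered) and specificity `SP = TN / (TN + FP)` (truly absent cells
#' recovered). SN (resp. SP) is `NA` when no cell is truly 1 (resp. 0).
#'
#' @param counts output of [confusion_counts()] (or any named vector with
#'   TP, TN, FP, FN).
#' @return one-row tibble: TP, TN, FP, FN, N, HD, SN, SP.
#' @export
structure_metrics <- function(counts) {
  counts <- counts[c("TP", "TN", "FP", "FN")]
  N <- sum(counts)
  if (N == 0) abort("no cells to compare (N = 0)")
  tibble::tibble(
    TP = counts[["TP"]], TN = counts[["TN"]],
    FP = counts[["FP"]], FN = counts[["FN"]], N = N,
    HD = (counts[["FP"]] + counts[["FN"]]) / N,
    SN = if (counts[["TP"]] + counts[["FN"]] > 0) {
      counts[["TP"]] / (counts[["TP"]] + counts[["FN"]])
    } else NA_real_,
    SP = if (counts[["TN"]] + counts[["FP"]] > 0) {
      counts[["TN"]] / (counts[["TN"]] + counts[["FP"]])
    } else NA_real_
  )
}

as_gene_list <- function(x) if (is.matrix(x)) list(x) else x

#' Pooled sensitivity/specificity curve over a threshold grid
#'
#' For each threshold, every gene's continuous structure is binarized, its
#' columns having been matched to the truth once (by L1 assignment on the
#' continuous values), and the confusion counts are pooled over genes before
#' converting to SN, SP and HD. Pooling makes SN non-increasing and SP
#' non-decreasing in the threshold by construction.
#'
#' @param G_true binary truth matrix or list of them (one per gene).
#' @param G_tilde continuous structure estimate(s), same length.
#' @param thresholds grid in (0, 1); default steps of 0.05.
#' @param match match predicted columns to truth first (default TRUE).
#' @return tibble: th, TP, TN, FP, FN, N, HD, SN, SP, FPR.
#' @export
roc_curve <- function(G_true, G_tilde, thresholds = seq(0.05, 0.95, by = 0.05),
                      match = TRUE) {
  truth <- as_gene_list(G_true)
  preds <- as_gene_list(G_tilde)
  if (length(truth) != length(preds)) abort("gene lists differ in length")
  if (any(thresholds <= 0 | thresholds >= 1)) abort("thresholds must lie in (0, 1)")
  matched <- purrr::map2(preds, truth, function(p, tr) {
    k <- max(ncol(p), ncol(tr))
    if (match) {
      perm <- match_transcript_columns(p, tr)
      list(pred = pad_columns(p, k)[, perm, drop = FALSE], truth = pad_columns(tr, k))
    } else {
      list(pred = pad_columns(p, k), truth = pad_columns(tr, k))
    }
  })
  rows <- purrr::map(thresholds, function(th) {
    counts <- c(TP = 0, TN = 0, FP = 0, FN = 0)
    for (g in matched) {
      counts <- counts + confusion_counts(g$truth, (g$pred > th) * 1)
    }
    dplyr::mutate(structure_metrics(counts), th = th, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, FPR = 1 - .data$SP)
}

#' Threshold where sensitivity equals specificity
#'
#' Finds, by linear interpolation along the threshold grid, the point where
#' the (isotonically cleaned) SN and SP curves cross; at that threshold a
#' false inclusion and a false exclusion of a probe are equally unlikely.
#'
#' @param curve tibble from [roc_curve()] (columns th, SN, SP).
#' @return list: `th` (crossing threshold), `value` (common SN = SP),
#'   `boundary` (TRUE when the curves never cross inside the grid and the
#'   nearest edge is returned), `tie` (TRUE when SN and SP coincide
#'   everywhere; the grid midpoint is returned).
#' @export
crossing_point <- function(curve) {
  th <- curve$th
  sn <- cummin(pmin(curve$SN, 1)) # enforce monotone shape against numeric dust
  sp <- cummax(pmax(curve$SP, 0))
  d <- sn - sp
  if (all(abs(d) < 1e-12)) {
    mid <- ceiling(length(th) / 2)
    return(list(th = th[mid], value = sn[mid], boundary = FALSE, tie = TRUE))
  }
  if (all(d > 0)) {
    warn("SN stays above SP on the whole grid; returning the upper boundary")
    return(list(th = th[length(th)], value = (sn[length(th)] + sp[length(th)]) / 2,
                boundary = TRUE, tie = FALSE))
  }
  if (all(d < 0)) {
    warn("SP stays above SN on the whole grid; returning the lower boundary")
    return(list(th = th[1], value = (sn[1] + sp[1]) / 2, boundary = TRUE, tie = FALSE))
  }
  i <- which(d <= 0)[1]
  if (d[i] == 0) {
    return(list(th = th[i], value = sn[i], boundary = FALSE, tie = FALSE))
  }
  # sign change between i-1 and i: interpolate d to zero
  w <- d[i - 1] / (d[i - 1] - d[i])
  th_star <- th[i - 1] + w * (th[i] - th[i - 1])
  value <- sn[i - 1] + w * (sn[i] - sn[i - 1])
  list(th = th_star, value = value, boundary = FALSE, tie = FALSE)
}

#' Splicing-call error rates from per-gene transcript counts
#'
#' A gene is "called spliced" when more than one transcript is estimated.
#' FPR: fraction of truly single-transcript genes called spliced. FNR:
#' fraction of truly multi-transcript genes called single-transcript.
#'
#' @param true_k,est_k paired integer vectors of true and estimated counts.
#' @return list: `FPR`, `FNR` (either `NA` when its class is empty).
#' @export
splicing_call_rates <- function(true_k, est_k) {
  if (length(true_k) != length(est_k)) abort("true_k and est_k must be paired")
  single <- true_k == 1
  multi <- true_k > 1
  list(
    FPR = if (any(single)) mean(est_k[single] > 1) else NA_real_,
    FNR = if (any(multi)) mean(est_k[multi] == 1) else NA_real_
  )
}

#' Mean absolute error of concentration estimates, in percent
#'
#' Concentrations out of the factorization are relative, so the estimate is
#' first rescaled by the single non-negative scalar minimizing the squared
#' error against the truth; the MAE is then normalized by the mean true
#' concentration.
#'
#' @param T_true,T_est matched concentration matrices (same shape, rows
#'   aligned by [match_transcript_columns()]).
#' @param align rescale the estimate by the optimal scalar (default TRUE).
#' @return MAE as a percentage of the mean true concentration.
#' @export
concentration_mae <- function(T_true, T_est, align = TRUE) {
  if (!all(dim(T_true) == dim(T_est))) abort("shape mismatch between concentration matrices")
  mu <- mean(T_true)
  if (mu <= 0) abort("mean true concentration is zero; MAE%% undefined")
  s <- 1
  if (align) {
    den <- sum(T_est^2)
    s <- if (den > 0) max(0, sum(T_true * T_est) / den) else 1
  }
  100 * mean(abs(T_true - s * T_est)) / mu
}
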