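#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted gene into one row per probe-transcript cell
#'
#' @param x a `gene_fit`.
#' @param ... unused.
#' @return tibble: probe_id, transcript, g_tilde (continuous membership),
#'   g (binary call, NA for columns dropped at the threshold), affinity.
#' @method tidy gene_fit
#' @export
tidy.gene_fit <- function(x, ...) {
  Gt <- x$G_tilde
  out <- tibble::tibble(
    probe_id = rep(rownames(Gt) %||% as.character(seq_len(nrow(Gt))), ncol(Gt)),
    transcript = rep(colnames(Gt) %||% paste0("tr_", seq_len(ncol(Gt))),
                     each = nrow(Gt)),
    g_tilde = as.numeric(Gt),
    affinity = rep(unname(x$A), ncol(Gt))
  )
  kept <- colnames(x$G) %||% character(0)
  out$g <- ifelse(
    out$transcript %in% kept,
    as.numeric(x$G[cbind(
      match(out$probe_id, rownames(x$G)),
      match(out$transcript, colnames(x$G))
    )]),
    NA_real_
  )
  out
}

#' One-row summary of a fitted gene
#'
#' @param x a `gene_fit`.
#' @param ... unused.
#' @return tibble: gene_id, n_probes, n_samples, k, k_estimated, loss,
#'   n_outliers, improvements.
#' @method glance gene_fit
#' @export
glance.gene_fit <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id,
    n_probes = nrow(x$G_tilde),
    n_samples = ncol(x$T),
    k = x$k,
    k_estimated = x$k_estimated,
    loss = x$loss,
    n_outliers = sum(x$outlier_mask),
    improvements = x$config$improvements
  )
}

#' Tidy per-transcript concentrations of a fitted gene
#'
#' @param fit a `gene_fit`.
#' @return tibble: transcript, sample, concentration (relative units).
#' @export
tidy_concentrations <- function(fit) {
  T_hat <- fit$T
  tibble::tibble(
    transcript = rep(rownames(T_hat) %||% paste0("tr_", seq_len(nrow(T_hat))),
                     ncol(T_hat)),
    sample = rep(colnames(T_hat) %||% as.character(seq_len(ncol(T_hat))),
                 each = nrow(T_hat)),
    concentration = as.numeric(T_hat)
  )
}

#' Plot the estimated structure and concentrations of a fitted gene
#'
#' Two-panel view mirroring how these fits are read in practice: a
#' probe-by-transcript membership heat map (continuous structure) and
#' per-sample concentration profiles per transcript.
#'
#' @param object a `gene_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gene_fit
#' @export
autoplot.gene_fit <- function(object, ...) {
  df <- tidy.gene_fit(object)
  df$probe_id <- factor(df$probe_id, levels = rev(rownames(object$G_tilde)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$transcript, y = .data$probe_id,
                                   fill = .data$g_tilde)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 1), name = "membership") +
    ggplot2::labs(
      title = sprintf("%s: continuous structure (k = %d)", object$gene_id, object$k),
      x = "transcript", y = "probe"
    ) +
    ggplot2::theme_minimal()
}

#' Plot transcript concentration profiles
#'
#' @param fit a `gene_fit`.
#' @return a ggplot object (lines per transcript across samples).
#' @export
plot_concentrations <- function(fit) {
  df <- tidy_concentrations(fit)
  df$sample <- factor(df$sample, levels = colnames(fit$T))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$concentration,
                                   group = .data$transcript,
                                   colour = .data$transcript)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "sample", y = "relative concentration") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot a pooled sensitivity/specificity/Hamming threshold sweep
#'
#' @param curve tibble from [roc_curve()].
#' @return a ggplot object with SN, SP and HD against the threshold.
#' @export
plot_threshold_curve <- function(curve) {
  long <- tibble::tibble(
    th = rep(curve$th, 3),
    metric = rep(c("SN", "SP", "HD"), each = nrow(curve)),
    value = c(curve$SN, curve$SP, curve$HD)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$th, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "threshold on continuous structure", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
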