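#' Simulate a probeset-coherent binary gene structure
#'
#' Draws a binary probes x transcripts structure in which all probes of a
#' probeset share one hybridization pattern (exon-array probes interrogate
#' the same exon or exon part, so a real isoform either contains all of them
#' or none). Patterns are Bernoulli draws biased toward inclusion
#' (`p_one = 0.7` by default: annotated isoforms of a gene share most of
#' their exons), rejection-sampled until every probe hybridizes somewhere,
#' every transcript carries at least one probe, and all transcript columns
#' are distinct.
#'
#' @param n_probesets number of probesets.
#' @param probes_per_probeset integer vector; each probeset's probe count is
#'   drawn uniformly from it (scalar = fixed count).
#' @param n_transcripts number of isoforms, 1..6.
#' @param p_one inclusion probability of a probeset in an isoform.
#' @param max_tries rejection-sampling budget.
#' @return list: `G` (binary matrix with probe rownames), `probeset`
#'   (character vector aligned to rows), `patterns` (probeset x transcript).
#' @export
simulate_structure <- function(n_probesets, probes_per_probeset = c(3, 4),
                               n_transcripts, p_one = 0.7, max_tries = 1000) {
  if (n_transcripts < 1 || n_transcripts > 6) {
    abort("n_transcripts must be between 1 and 6")
  }
  if (n_probesets < 1) abort("need at least one probeset")
  ppp <- if (length(probes_per_probeset) == 1) {
    rep(probes_per_probeset, n_probesets)
  } else {
    sample(seq(min(probes_per_probeset), max(probes_per_probeset)),
           n_probesets, replace = TRUE)
  }
  if (n_transcripts == 1) {
    patterns <- matrix(1, n_probesets, 1)
  } else {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      patterns <- matrix(
        as.numeric(runif(n_probesets * n_transcripts) < p_one),
        n_probesets, n_transcripts
      )
      # a probeset present in no isoform cannot exist; resample those rows
      zero_rows <- rowSums(patterns) == 0
      patterns[zero_rows, ] <- 1
      distinct <- ncol(patterns) == ncol(unique(patterns, MARGIN = 2))
      if (all(colSums(patterns) > 0) && distinct) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort("could not build distinct non-empty transcript columns; request infeasible")
    }
  }
  probeset <- rep(paste0("ps_", seq_len(n_probesets)), times = ppp)
  G <- patterns[rep(seq_len(n_probesets), times = ppp), , drop = FALSE]
  rownames(G) <- paste0("probe_", seq_len(nrow(G)))
  colnames(G) <- paste0("tr_", seq_len(n_transcripts))
  list(G = validate_structure(G), probeset = probeset, patterns = patterns)
}

#' Simulate transcript concentrations
#'
#' Concentrations follow the uniform-times-uniform scheme: per-sample values
#' are Uniform(0,1) draws multiplied by a per-transcript scale factor, itself
#' Uniform(0,1). This makes some isoforms of a gene systematically less
#' expressed than others in every sample, as observed in real data.
#'
#' @param n_transcripts,n_samples dimensions.
#' @return transcripts x samples matrix with entries in `[0,1]`; the
#'   per-transcript factors are attached as attribute `factor`.
#' @export
simulate_concentrations <- function(n_transcripts, n_samples) {
  if (n_transcripts < 1 || n_samples < 1) abort("dimensions must be >= 1")
  f <- runif(n_transcripts)
  U <- matrix(runif(n_transcripts * n_samples), n_transcripts, n_samples)
  T_mat <- U * f
  rownames(T_mat) <- paste0("tr_", seq_len(n_transcripts))
  colnames(T_mat) <- paste0("sample_", seq_len(n_samples))
  attr(T_mat, "factor") <- f
  T_mat
}

#' Simulate per-probe affinities
#'
#' Probe affinities (the proportionality constant between analyte
#' concentration and measured intensity) are log-normal:
#' `a_i = exp(N(mu, sigma))` with defaults `mu = log(100)`, `sigma = 1`,
#' emulating the heavy-tailed affinity spread of real probes.
#'
#' @param n_probes number of probes.
#' @param meanlog,sdlog log-normal parameters.
#' @return positive numeric vector of length `n_probes`.
#' @export
simulate_affinities <- function(n_probes, meanlog = log(100), sdlog = 1) {
  if (n_probes < 1) abort("n_probes must be >= 1")
  a <- exp(rnorm(n_probes, meanlog, sdlog))
  names(a) <- paste0("probe_", seq_len(n_probes))
  a
}

#' Noise parameters for the probe-signal simulator
#'
#' @param sigma_mult standard deviation of multiplicative noise on the
#'   natural-log scale.
#' @param sigma_add_frac additive-noise standard deviation expressed as a
#'   fraction of the median clean signal.
#' @return list of class `noise_params`.
#' @export
noise_params <- function(sigma_mult = 0.20, sigma_add_frac = 0.05) {
  if (sigma_mult < 0 || sigma_add_frac < 0) abort("noise parameters must be >= 0")
  structure(list(sigma_mult = sigma_mult, sigma_add_frac = sigma_add_frac),
            class = "noise_params")
}

#' Build a noisy probe signal matrix from affinities, structure and concentrations
#'
#' Clean signal is `Y0 = diag(A) G T` (probe signal proportional to affinity
#' times the summed concentration of the isoforms the probe hybridizes to).
#' Multiplicative log-normal noise and additive Gaussian noise (scaled to the
#' median clean signal) are applied; negatives are clipped to 0.
#'
#' @param A affinity vector (length = probes).
#' @param G binary structure, probes x transcripts.
#' @param T_mat concentrations, transcripts x samples.
#' @param noise [noise_params()].
#' @return probes x samples matrix; clean signal attached as attr `clean`.
#' @export
simulate_probe_signal <- function(A, G, T_mat, noise = noise_params()) {
  if (length(A) != nrow(G)) abort("length(A) must equal nrow(G)")
  if (ncol(G) != nrow(T_mat)) abort("ncol(G) must equal nrow(T)")
  clean <- (A * G) %*% T_mat
  Y <- clean
  if (noise$sigma_mult > 0) {
    Y <- Y * exp(matrix(rnorm(length(Y), 0, noise$sigma_mult), nrow(Y)))
  }
  if (noise$sigma_add_frac > 0) {
    Y <- Y + matrix(rnorm(length(Y), 0, noise$sigma_add_frac * median(clean)), nrow(Y))
  }
  Y <- pmax(Y, 0)
  dimnames(Y) <- dimnames(clean)
  attr(Y, "clean") <- clean
  Y
}

#' Simulate one gene with known truth
#'
#' @param n_transcripts isoform count (1..6).
#' @param n_samples number of samples.
#' @param n_probesets number of probesets (default drawn uniformly in 8..15).
#' @param probes_per_probeset range of probes per probeset.
#' @param noise [noise_params()].
#' @param gene_id identifier used in the annotation.
#' @param seed optional seed (does not disturb the caller's RNG stream).
#' @return list of class `synthetic_gene` with `Y`, `Y0`, `A`, `G`, `T`,
#'   `probeset`, `annotation`, `n_transcripts`, `seed`.
#' @export
simulate_gene <- function(n_transcripts, n_samples = 33, n_probesets = NULL,
                          probes_per_probeset = c(3, 4), noise = noise_params(),
                          gene_id = "gene_1", seed = NULL) {
  with_seed_opt(seed, {
    if (is.null(n_probesets)) n_probesets <- 8:15
    if (length(n_probesets) > 1) n_probesets <- sample(n_probesets, 1)
    st <- simulate_structure(n_probesets, probes_per_probeset, n_transcripts)
    A <- simulate_affinities(nrow(st$G))
    T_mat <- simulate_concentrations(n_transcripts, n_samples)
    Y <- simulate_probe_signal(A, st$G, T_mat, noise)
    annotation <- tibble::tibble(
      probe_id = rownames(st$G),
      probeset_id = st$probeset,
      gene_id = gene_id,
      chrom = "chrS",
      start = 1000L + 100L * seq_len(nrow(st$G)),
      end = 1000L + 100L * seq_len(nrow(st$G)) + 24L,
      strand = "+"
    )
    structure(
      list(
        gene_id = gene_id, Y = Y, Y0 = attr(Y, "clean"), A = A, G = st$G,
        T = T_mat, probeset = st$probeset, annotation = annotation,
        n_transcripts = n_transcripts, seed = seed
      ),
      class = "synthetic_gene"
    )
  })
}

#' @export
print.synthetic_gene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_gene> %s: %d probes x %d samples, %d transcript(s)\n",
    x$gene_id, nrow(x$Y), ncol(x$Y), x$n_transcripts
  ))
  invisible(x)
}

#' Default simulation configuration
#'
#' Mirrors the published simulation scale: hundreds of genes with one to six
#' isoforms over 33 samples (11 tissues x 3 replicates).
#'
#' @param n_genes number of genes.
#' @param n_samples samples per gene.
#' @param transcript_counts candidate isoform counts, sampled uniformly.
#' @param n_probesets range of probesets per gene.
#' @param probes_per_probeset range of probes per probeset.
#' @param sigma_mult,sigma_add_frac noise magnitudes (see [noise_params()]).
#' @param seed master seed; per-gene seeds are derived deterministically.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 600, n_samples = 33, transcript_counts = 1:6,
                       n_probesets = 8:15, probes_per_probeset = c(3, 4),
                       sigma_mult = 0.20, sigma_add_frac = 0.05, seed = 1) {
  structure(
    list(
      n_genes = n_genes, n_samples = n_samples,
      transcript_counts = transcript_counts, n_probesets = n_probesets,
      probes_per_probeset = probes_per_probeset,
      sigma_mult = sigma_mult, sigma_add_frac = sigma_add_frac, seed = seed
    ),
    class = "sim_config"
  )
}

check_config <- function(config) {
  if (!inherits(config, "sim_config")) {
    known <- names(formals(sim_config))
    bad <- setdiff(names(config), known)
    if (length(bad) > 0) {
      abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
    }
    config <- do.call(sim_config, config)
  }
  config
}

#' Simulate a dataset of genes with known truth
#'
#' Fully reproducible: each gene's seed is derived from the master seed, so
#' the same configuration yields a bit-identical dataset.
#'
#' @param config a [sim_config()] or a plain list of its arguments (unknown
#'   keys are an error).
#' @return list of class `synthetic_dataset`: `genes` (list of
#'   `synthetic_gene`), `config`, `manifest` (tibble: gene_id, n_transcripts,
#'   n_probes, n_samples, seed).
#' @export
simulate_dataset <- function(config = sim_config()) {
  config <- check_config(config)
  noise <- noise_params(config$sigma_mult, config$sigma_add_frac)
  genes <- vector("list", config$n_genes)
  counts <- integer(config$n_genes)
  if (config$n_genes > 0) {
    counts <- with_seed_opt(config$seed, {
      sample(config$transcript_counts, config$n_genes, replace = TRUE)
    })
    for (i in seq_len(config$n_genes)) {
      genes[[i]] <- simulate_gene(
        n_transcripts = counts[i], n_samples = config$n_samples,
        n_probesets = config$n_probesets,
        probes_per_probeset = config$probes_per_probeset,
        noise = noise, gene_id = sprintf("gene_%04d", i),
        seed = derive_seed(config$seed, i)
      )
    }
  }
  manifest <- tibble::tibble(
    gene_id = vapply(genes, function(g) g$gene_id, character(1)),
    n_transcripts = vapply(genes, function(g) g$n_transcripts, integer(1)),
    n_probes = vapply(genes, function(g) nrow(g$Y), integer(1)),
    n_samples = vapply(genes, function(g) ncol(g$Y), integer(1)),
    seed = vapply(genes, function(g) as.integer(g$seed), integer(1))
  )
  structure(list(genes = genes, config = config, manifest = manifest),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d gene(s), %d sample(s), seed %s\n",
    length(x$genes), x$config$n_samples, x$config$seed
  ))
  invisible(x)
}
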