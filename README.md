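# isodeconv

Transcript isoform structure and concentration deconvolution from exon
array probe intensities.

## The problem

Exon arrays probe every exon of a gene, but the analyte of biological
interest is the transcript isoform. When a gene is alternatively spliced,
most probes hybridize against several isoforms at once, so grouping probes
by transcript and summarizing them like an expression array discards or
corrupts exactly the probes that distinguish isoforms. isodeconv is for
analysts who have a background-removed, normalized probe-by-sample
intensity matrix for a gene and want to know (a) how many isoforms are
expressed, (b) which probes belong to which isoform — including isoforms
missing from annotation — and (c) each isoform's relative concentration
per sample.

## The model and the method

The generative model is the affinity deconvolution model

    Y ≈ A · G · T

with `Y` the probes × samples intensities, `A` a diagonal matrix of
per-probe affinities, `G` a binary probes × transcripts structure matrix
and `T` the transcripts × samples concentrations. The estimation core is
non-negative matrix factorization, `Y ≈ W·H`, identifying `W` with `A·G`
and `H` with `T`, wrapped in four improvements:

* **outlier correction** — resampled bi-cross-validation estimates every
  entry from held-out blocks and replaces entries far from their estimate
  median (they otherwise hijack factors);
* **rank estimation** — the number of transcripts is the smallest rank
  whose bi-cross-validation error (250 random 2×2 block partitions,
  `P ≈ Q·S_k⁺·R` reconstruction) is not statistically larger than the
  minimum-error rank's, by a one-sided Wilcoxon test;
* **Adapt gauge fixing** — NMF is unique only up to a diagonal rescale
  `(W·D)(D⁻¹·H)`; `D` is chosen to minimize the robust L1 objective
  `Σ_i Σ_{j<k} |log(d_j W_ij) − log(d_k W_ik)|` so that `W·D` mimics the
  `A·G` pattern; affinities are then row maxima and the continuous
  structure is `G̃ = Ã⁻¹·W̃ ∈ [0,1]`;
* **probeset coherence** — probes of one probeset target the same exon, so
  their structure rows are forced to a common (rounded mean) pattern.

A simulator reproducing the published synthetic evaluation (known `A`,
`G`, `T`; multiplicative + additive noise; 33 samples; 1–6 isoforms) and
the full scoring stack (confusion counts, Hamming distance, sensitivity/
specificity threshold sweeps, crossing points, splicing-call error rates,
concentration MAE%) are included, so every stage is testable offline.

## Worked example

```r
library(isodeconv)

gene <- simulate_gene(n_transcripts = 2, n_samples = 33, seed = 7)
fit  <- run_gene(gene$Y, gene$annotation, fit_config(n_restarts = 5, seed = 11))
fit
#> <gene_fit> gene_1: 32 probes x 33 samples -> 2 transcript(s) (estimated), loss 22.87

perm <- match_transcript_columns(fit$G_tilde, gene$G)
structure_metrics(confusion_counts(gene$G, (fit$G_tilde[, perm] > 0.5) * 1))
#> # A tibble: 1 × 8
#>      TP    TN    FP    FN     N    HD    SN    SP
#> 1    46    18     0     0    64     0     1     1

sapply(1:2, function(j) cor(fit$T[perm, ][j, ], gene$T[j, ]))
#> [1] 0.985 0.973
```

The fit estimated two isoforms from the intensities alone, recovered the
binary structure perfectly (Hamming distance 0, sensitivity and
specificity 1 over the 64 probe × transcript cells) and produced
concentration profiles correlating 0.97–0.99 with the simulated truth
(concentrations are relative, so they are compared up to scale).
`autoplot(fit)` draws the continuous structure as a heat map,
`plot_concentrations(fit)` the per-sample isoform abundances, and
`tidy(fit)`/`glance(fit)` expose everything as tibbles.

A thin command-line front end ships in `inst/cli/isodeconv.R`
(`simulate`, `fit`, `rank`, `evaluate` subcommands over TSV/JSON files).

## Limitations

Concentrations are identified only up to a per-gene scale; splicing events
that split a probeset are invisible to the coherence correction (disable
it with `coherence = FALSE`); performance degrades beyond 4–5 concurrent
isoforms. See the methods vignette
(`vignettes/isoform-deconvolution.Rmd`) for the model assumptions,
identifiability limits and every numerical choice.
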