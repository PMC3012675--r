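Package: isodeconv
Title: Transcript Isoform Structure and Concentration Deconvolution from
    Exon Array Probe Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs which probes belong to which transcript isoform of
    a gene (including unannotated isoforms) and estimates per-sample isoform
    concentrations from a non-negative probe-by-sample intensity matrix.
    The core is a non-negative matrix factorization (NMF) of the probe
    signal, improved by bi-cross-validation to select the number of
    transcripts and to detect and correct outlier intensities, a robust
    diagonal rescaling of the factors that resolves the NMF gauge freedom
    toward the affinity-times-binary-structure model, and a probeset
    coherence correction that exploits the redundancy of exon array probe
    groupings. A simulator generating genes with known affinities,
    structure and concentrations, plus the structure/concentration scoring
    used to evaluate the method, are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    MASS,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
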