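Package: acetylscope
Title: Quantitative Acetylome Analysis for Deacetylase Target Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for downstream analysis of site-level
    lysine-acetylome quantification from paired deacetylase knockdown and
    overexpression experiments. Provides left-censored (Gaussian downshift)
    imputation of label-free intensities, normalization of acetyl-site fold
    changes to global protein abundance, threshold-based classification of
    direct and indirect deacetylase targets by anti-correlation across the
    two arms, a sliding-threshold false-positive-rate estimator with
    scrambled-null control schemes, greedy motif extraction with binomial
    significance against a proteome background, signed residue-by-position
    Fisher-exact enrichment heatmaps, and Fisher-exact gene-set
    over-representation analysis. A synthetic-acetylome generator with
    planted targets and intensity-dependent missingness makes the whole
    pipeline runnable and testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
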