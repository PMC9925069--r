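Package: cismr
Title: Cis-Instrument Two-Sample Mendelian Randomisation for Drug-Target Proxies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for cis-instrument two-sample Mendelian
    randomisation of drug-target perturbation (e.g. IL6R blockade proxied by
    CRP-lowering variants) on binary disease outcomes. Provides GWAS
    summary-statistic input and harmonisation onto shared effect alleles,
    cis-window instrument selection with greedy LD pruning, Wald-ratio and
    inverse-variance-weighted estimation with first-order weights, an MR-Egger
    and bootstrap weighted-median sensitivity suite, radial outlier detection,
    leave-one-out analysis, noise-augmented directional clustering of SNP
    effects across traits, fixed-effects meta-analysis of per-cohort odds
    ratios, a configuration-driven pipeline runner, and a calibrated synthetic
    summary-statistics generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    metafor,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
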