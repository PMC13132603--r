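Package: mrmediate
Title: Summary-Statistics Mendelian Randomization, Mediation, Colocalization
    and Single-Cell Gene-Set Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for two-sample Mendelian randomization
    (MR) from GWAS summary statistics: instrument selection (significance
    filter, greedy LD clumping, F-statistic screen, confounder blacklist),
    allele harmonization, the standard estimator battery (Wald ratio,
    inverse-variance weighted, MR-Egger, weighted median, weighted and simple
    mode), sensitivity diagnostics (Cochran's Q, Egger intercept,
    MR-PRESSO-style outlier resampling, leave-one-out), multivariable MR and
    product-of-coefficients mediation, Bayesian colocalization via Wakefield
    approximate Bayes factors, and a single-cell stage that scores gene-set
    activity per cell, stratifies cells at the median score, and tests
    differential expression by Wilcoxon rank-sum. Seeded generators simulate
    GWAS summary-statistic triplets under a known exposure-mediator-outcome
    causal structure and single-cell counts with known gene-set activity, so
    every stage of the five-stage discovery, replication, bidirectional,
    multivariable and mediation workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    Matrix,
    purrr,
    readr,
    rlang,
    withr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
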