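Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening and Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for two-sample Mendelian
    randomization (MR) with GWAS summary statistics: genetic instrument
    selection with greedy LD clumping and F-statistic strength checks,
    exposure-outcome harmonization to a common effect-allele coding
    (including palindromic-variant handling), causal-effect estimation by
    Wald ratio, inverse-variance-weighted meta-analysis with fixed or
    random effects, MR-Egger regression, the weighted median, and
    mode-based estimators, heterogeneity and pleiotropy diagnostics
    (Cochran's Q, I-squared, Egger intercept, Steiger directionality),
    multi-exposure screening with Bonferroni correction and replication,
    and two-step mediation MR with product-of-coefficients indirect
    effects and Delta-method standard errors. Ships a synthetic GWAS
    summary-statistics generator with known causal ground truth so every
    stage of the pipeline can be exercised and validated without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
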