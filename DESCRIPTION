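Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-sample Mendelian
    randomization with GWAS summary statistics: reading and validating
    consortium-style association tables, selecting independent
    genome-wide-significant instruments (LD pruning and proxy
    substitution), harmonizing effect alleles across studies (allele
    swaps, strand flips, palindromic variants), and estimating causal
    effects with the inverse-variance-weighted, weighted-median and
    MR-Egger estimators, including the Egger intercept test for
    directional pleiotropy and Bonferroni-adjusted reporting.  A
    synthetic summary-statistics generator with known ground truth
    (causal effect, pleiotropy regime, LD blocks, allele-coding
    corruption) makes every pipeline stage testable without access to
    consortium data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
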