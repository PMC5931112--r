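Package: mrgls
Title: Two-Sample Mendelian Randomisation with LD-Aware Generalised Least
    Squares, Pleiotropy Filtering and Bayesian Null Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-sample Mendelian
    randomisation from GWAS summary statistics. Reads and harmonises
    per-SNP association records, selects independent genome-wide
    significant instruments by greedy LD pruning (with proxy-SNP support),
    pools per-SNP Wald ratios by generalised least squares under an LD
    correlation matrix, detects horizontally pleiotropic instruments with a
    HEIDI-style outlier test, computes a priori power for binary outcomes,
    and evaluates null findings via Wakefield approximate Bayes factors and
    the minimum prior probability of association needed for a given
    Bayesian false null probability. Includes a synthetic two-sample
    summary-statistic generator with known ground truth for end-to-end
    testing, and a config-driven pipeline runner.
License: MIT
Encoding: UTF-8
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
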