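Package: epiroc
Title: Exact ROC-Based Detection of Epistatic SNP Interactions in
    Case-Control GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-free detection of epistatic SNP-pair interactions in
    case-control genome-wide association studies.  Implements exact
    hypothesis tests built on prevalence-mapping ROC curves: the
    sensitivity-and-specificity (SS) test, the gain-in-sensitivity-and-
    specificity (GSS) test against a pair-specific convex null region, and
    the fast difference (DSS) proxy filter, together with baseline
    chi-square and Fisher exact filters, an exhaustive two-stage pairwise
    scan engine over PLINK-format genotype data, and a synthetic-data
    simulator with a power and false-positive-rate evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
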