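Package: imputebias
Title: Reference-Panel Bias in Genotype Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and assessment of allele-directional bias introduced
    by genotype imputation when the phased reference panel does not match the
    phenotype of the query samples. Provides a seedable case/control cohort
    simulator with block-like linkage disequilibrium and a known risk
    architecture, a diploid haplotype-copying (Li-Stephens) imputation engine
    with exact forward-backward posteriors, per-variant quality control
    (minor-allele frequency, exact Hardy-Weinberg test in controls, call
    rate), stratified cohort splitting, logistic association scans, and the
    mask-and-impute discordance, bias and odds-ratio deflation statistics
    used to quantify how reference-panel choice distorts imputed genotypes
    and downstream effect-size estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
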