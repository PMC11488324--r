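Package: mtscatac
Title: Single-Cell Mitochondrial Genotyping and Chromatin Accessibility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for joint single-cell mitochondrial DNA (mtDNA) and chromatin
    accessibility (mtscATAC-seq) analysis: per-cell strand-resolved allele
    counting on the mitochondrial genome, pseudo-bulk aggregation, a
    multi-stage variant filtering cascade with per-filter audit flags,
    mitochondrial variant annotation under the vertebrate mitochondrial
    genetic code, per-cell quality control (TSS enrichment, FRiP, unique
    fragment counts), barnyard collision and contamination estimation,
    mtDNA-content and mutation-burden cohort statistics with exact Wilcoxon
    rank-sum tests, carrier-versus-wild-type differential accessibility with a
    permutation null, PWM motif scanning with hypergeometric enrichment, and a
    seeded synthetic-data generator that emulates the statistical structure of
    mtscATAC-seq experiments so every stage is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
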