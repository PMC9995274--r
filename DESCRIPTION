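Package: gmrtrio
Title: Pedigree-Based Germline Mutation Rate Estimation and Comparative Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates germline mutation rates from parent-offspring trios.
    Implements a five-filter cascade for calling de novo point mutations from
    all-sites trio genotype tables, callable-genome and false-negative-rate
    corrected per-generation rates with Wilson confidence intervals,
    read-backed parent-of-origin phasing with male-bias (alpha) estimation,
    a Poisson parental-age model with a mutational contribution at birth that
    yields modelled rates at species generation time, strand-collapsed
    mutation-spectrum statistics, and phylogenetically controlled regressions
    against life-history traits and effective population size. A synthetic
    cohort generator emulates trio sequencing summaries, phasing evidence,
    time-calibrated trees and piecewise-constant Ne histories so the whole
    pipeline is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    vcfR
Suggests:
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
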