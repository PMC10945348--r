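Package: immunosig
Title: Multi-Cell-Type Gene Signatures for Predicting Anti-PD-1 Response
Version: 0.1.0
Authors@R:
    person("Immunosig", "Developers", email = "maintainer@immunosig.org",
           role = c("aut", "cre"))
Description: A tested pipeline for deriving tumor-microenvironment cell-subgroup
    marker genes from single-cell expression data, inferring copy-number
    variation profiles from positional moving averages of expression,
    constructing immunotherapy-response gene signatures by intersecting
    subgroup markers with bulk differential expression, training a grid of
    seven machine-learning classifiers with repeated stratified
    cross-validation, and stratifying survival by predicted response. Ships a
    synthetic-data generator that emulates the statistical structure of a
    multi-patient single-nucleus RNA-seq study and a pooled immune-checkpoint
    inhibitor bulk cohort, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
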