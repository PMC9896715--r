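Package: multiregDE
Title: Per-Patient Differential Expression and Prognostic Stratification
    for Multi-Region Tumour RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multi-region tumour RNA-seq cohorts in
    which each patient contributes several tumour regions and one adjacent
    normal sample.  Implements paired per-patient negative-binomial Wald
    differential expression, aggregation of per-patient calls into the
    differentially-expressed-patient-count (DEPC) statistic with AP/NAP
    gene classification, categorical latent block model co-clustering of
    patients into prognostic groups, weighted log-rank (Peto-Peto family)
    survival comparisons, hypergeometric gene-set over-representation, and
    a trial-ensemble multilayer-perceptron transfer classifier on
    tumour-normal-difference features.  A synthetic cohort generator with
    planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    MASS,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
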