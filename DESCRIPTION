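Package: ibwgp
Title: Genetic Evaluation and Genomic Prediction for Piglet Birth Weight
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based genetic evaluation and genomic prediction for
    individual birth weight (IBW) in pigs. Implements REML animal models with
    maternal genetic and common-litter effects on the numerator relationship
    matrix, likelihood-ratio model comparison, BLUP breeding values with
    PEV-based reliabilities, deregression of breeding values (excluding or
    including parent average) with per-record weighting factors, weighted
    BayesB/BayesC Gibbs samplers over -10/0/10 coded marker panels, 1-Mb
    window decomposition of posterior genetic variance for association
    scans, and relationship-aware k-means cross-validation of direct genomic
    values. A gene-dropping simulator generates pedigrees, SNP panels and
    phenotypes with the matching variance structure for testing and power
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
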