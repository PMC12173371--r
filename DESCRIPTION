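Package: landrace
Title: Environmental Adaptation and Genomic Prediction for Traditional Crop Varieties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing environmental adaptation in georeferenced
    panels of traditional crop varieties (landraces) evaluated in common-garden
    testcross trials. Provides genotype input and quality control, genomic
    relationship matrices with leave-one-chromosome-out variants, rank-based
    inverse normal transforms of environmental variables, a hierarchical
    Bayesian quadratic transfer-distance model of yield against
    environment-of-origin, multivariate genomic prediction of environment with
    random and spatially buffered cross-validation, joint multivariate
    genotype-environment and phenotype association scans with
    Kronecker-structured error covariance, greedy LD clumping with MAF-matched
    enrichment testing, a benchmark of genomic and environment-of-origin
    prediction models, and a synthetic-data generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    emmeans,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags,
    vcfR,
    optparse
Config/testthat/edition: 3
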