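Package: gwaspred
Title: GWAS-Assisted Genomic Prediction for Structured Breeding Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction studies in structured crop
    breeding panels. Simulates inbred panels with subpopulation structure,
    linkage disequilibrium and known trait architecture; reads and filters
    VCF genotypes; derives per-line BLUP phenotypes from replicated
    multi-year trials; characterizes populations (LD decay, windowed
    Weir-Cockerham Fst, genotype PCA, genetic distances); runs an
    EMMAX-style kinship-corrected mixed-linear-model GWAS with QTL-region
    calling; builds marker feature sets by GWAS significance thresholds,
    PCA and CDS subsampling; and benchmarks GBLUP, Bayesian Lasso, kernel
    ridge, random-forest and gradient-boosted-tree predictors under k-fold
    cross-validation with Gaussian-process Bayesian hyperparameter tuning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    lme4,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    optparse,
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
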