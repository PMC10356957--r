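Package: sparsepgs
Title: Sparse Polygenic Score Training, Evaluation and Biobank Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and characterizing sparse polygenic score (PGS)
    predictors at biobank scale. Implements a full pipeline: synthetic
    genotype/phenotype simulation under Hardy-Weinberg equilibrium with a
    configurable minor-allele-frequency spectrum, LD blocks, sparse additive
    architectures, liability-threshold case-control traits, full-sibling pairs
    and Balding-Nichols ancestry drift; quality control, sex-specific
    z-scoring and covariate adjustment; LASSO / elastic-net regularization-path
    training over nested training-size ladders with validation-set
    hyperparameter selection and cross-validation; a metric suite (AUC with
    Hanley-McNeil errors, correlation, inclusive odds ratios, sibling
    selection tests, single-SNP variance, variance-explained estimates);
    detection of compressed-sensing (Donoho-Tanner) phase-transition behavior
    in predictor sparsity; and projection of metric growth to larger biobanks
    by fitting bounded four-parameter growth curves with Cholesky-based
    Monte-Carlo uncertainty bands.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
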