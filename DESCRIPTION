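Package: pansense
Title: Swarm-Optimized Feature Selection for Pan-Genome Sensory Phenotype Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts electronic-nose and electronic-tongue sensory phenotypes of
    fermented milk from binary pan-genome variant matrices (SNP, gene
    presence/absence, intergenic region) of Lactococcus lactis.  A Dung Beetle
    Optimizer tunes a serialized four-stage feature-selection pipeline (variance
    threshold, univariate F selection, recursive feature elimination with
    cross-validation, principal component analysis); ten candidate regressors are
    compared under 10-fold cross-validation; and feature importance is
    back-projected through PCA loadings onto the original genomic features.
    Includes a synthetic genotype/phenotype generator with planted causal
    features and controllable causal-set overlap, descriptive sensory analytics
    (Spearman correlation, shared-feature counts), readers and writers for
    Roary-style Rtab matrices, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    withr,
    glmnet,
    e1071,
    ranger,
    rpart,
    xgboost,
    caret,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
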