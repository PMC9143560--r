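Package: metssr
Title: Metabolomic Severity Scores via Adaptive LASSO
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds metabolomic severity scores (metSS) for continuous
    clinical outcomes from untargeted plasma metabolomics profiled in two
    cohorts. Implements the full pipeline: within-batch median
    normalization, subject-level quality control, missingness tiering with
    present/absent dichotomization, k-nearest-neighbour imputation,
    cross-cohort feature harmonization, ridge-initialized adaptive LASSO
    fit by coordinate descent with per-feature penalty factors and
    per-observation weights, 10-fold cross-validation of the penalty,
    train/validation evaluation of variance explained (Wherry adjusted
    R-squared, mean squared error, partial F tests), sensitivity analyses
    (cohort swap, extreme-quintile weighting), and hypergeometric pathway
    over-representation with topology-based pathway impact. Includes a
    synthetic two-cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    fgsea,
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
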