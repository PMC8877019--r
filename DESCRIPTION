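Package: cellrules
Title: Interpretable Cell-Type Classification by Incremental Feature
    Selection and Decision-Rule Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workflow for annotating cell types from labeled single-cell
    expression matrices with interpretable models. Genes are ranked by
    gradient-boosted-tree split-count importance, nested feature subsets are
    evaluated by incremental feature selection with stratified 10-fold
    cross-validation and in-fold SMOTE class balancing, optimal decision-tree
    and random-forest classifiers are selected by weighted F1, and IF-THEN
    classification rules with passed counts are mined from the optimal
    decision tree. Includes a synthetic single-cell data generator with
    planted type-specific markers and strongly imbalanced class sizes, and a
    noise-perturbation robustness protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    ranger,
    stats,
    utils,
    withr,
    xgboost
LinkingTo: Rcpp
Suggests:
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
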