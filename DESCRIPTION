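Package: pairsel
Title: Pairwise Pre-Evaluation for Feature Selection in High-Dimensional
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection for microarray-style classification problems
    using pairwise pre-evaluation: every pair of features is scored by its
    cross-validated two-feature classification accuracy, and the resulting
    pair table is used to modify classic filter rankings (Chi-squared, Gain
    ratio, ReliefF, FSDD), greedy subset searches (forward search, backward
    elimination), and mRMR so that feature interactions inform the selection.
    Includes mutual-information pre-filtering, leave-one-out evaluation with
    linear SVM, k-nearest-neighbour, naive Bayes and random forest
    classifiers, a synthetic-data generator with planted interaction
    structure, and a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: C++17
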