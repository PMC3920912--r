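Package: mlrestore
Title: Multilabel Classification with Missing-Label Restoration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multilabel classification when training labels are
    incomplete (false negatives only). Restores missing document-category
    pairs with two similarity-based algorithms -- weighted k-nearest-neighbour
    voting and graph-regularized soft supervised learning (alternating
    minimization of a Kullback-Leibler misalignment objective) -- then
    modifies the training set ("add" new positives or "del" documents from a
    label's negatives), trains Binary-Relevance classifiers (linear
    large-margin or random forest) with per-label threshold tuning, and
    evaluates with micro-averaged precision/recall/F1 and CROC curves.
    Includes a label-deletion corruption simulator, a synthetic cluster-based
    multilabel data generator, readers and writers for Mulan-style ARFF,
    MatrixMarket and TSV multilabel formats, and an end-to-end experiment
    pipeline with dev-set grid search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    e1071,
    randomForest,
    foreign,
    xml2,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
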