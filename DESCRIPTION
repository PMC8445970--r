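Package: qsarselect
Title: Descriptor Selection and Classification for QSAR Screening Campaigns
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Machine-learning pipeline for discovering small sets of
    molecular descriptors that classify screening compounds, e.g. as
    toxic versus non-toxic or as circadian-period lengtheners versus
    no-changers. Reads PaDEL/ChemDes-style descriptor tables into a
    SummarizedExperiment-derived container, removes constant and
    non-finite descriptors, weights classes inversely to their sizes,
    ranks descriptors by recursive feature elimination under four
    tree-ensemble estimator families, tunes hyperparameters by grid
    search over replicated stratified 10-fold cross-validation, prunes
    the selected set by greedy backward elimination, and validates the
    final model with high-replication cross-validation. A synthetic
    descriptor-table generator with recorded ground truth makes every
    stage testable without external data, and a rule-based
    drug-likeness filter reproduces the library pre-screen used ahead
    of docking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    rpart,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
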