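Package: cslv
Title: Chromosome-Scale Length Variation Features from SNP Array Log R Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes chromosome-scale length variation (CSLV), a compact
    genome representation obtained by averaging SNP-array log R ratios over
    fixed segments of each autosome, and evaluates its power to predict
    phenotypes. Provides readers and writers for marker manifests and long-
    or wide-format log R ratio tables, fixed-partition chromosome
    segmentation with complete-case filtering, a synthetic SNP-array cohort
    simulator with group-, sex- and copy-number-driven dosage shifts and a
    heritable height model, and a machine-learning evaluation harness:
    cross-validated multi-family model search with stacked ensembles and a
    leaderboard, repeated-holdout ROC/AUC classification, height regression
    with a ranked grouped-mean curve, and permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    data.table,
    glmnet,
    xgboost,
    ranger,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
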