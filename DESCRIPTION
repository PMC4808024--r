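Package: pasflow
Title: Pathway Activation Strength Profiling of Melanoma Progression
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores signaling and metabolic pathway activation from bulk
    expression matrices using case-to-normal ratios gated by tolerance
    intervals, discriminates skin, nevus, primary and metastatic melanoma
    classes with a panel of machine-learning classifiers under repeated
    cross-validation, selects consensus discriminating pathways by
    importance-rank intersection and Kruskal-Wallis filtering, tabulates
    UP/DOWN direction signatures across progression contrasts, and detects
    co-activation modules of pathways. Ships a synthetic-data generator with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    limma,
    caret,
    e1071,
    randomForest,
    glmnet,
    MASS,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
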