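Package: rxnproto
Title: Few-Shot Meta-Learning for Enantioselectivity Prediction in
    Asymmetric Hydrogenation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Prototypical-network meta-learning for classifying
    transition-metal-catalyzed asymmetric olefin hydrogenation reactions as
    high or low enantioselectivity from small support sets. Provides a
    composite reaction featurization (512-bit radius-2 circular fingerprints
    or message-passing graph embeddings for olefin, ligand and solvent,
    concatenated with metal and additive one-hot encodings and reaction
    conditions), episodic task construction by random partitioning or by
    UMAP plus k-means clustering of the reaction space, an episodically
    trained prototypical network with three meta-test support protocols,
    single-task baselines (random forest, graph neural network, SVM,
    gradient boosting), AUPRC/AUROC evaluation with repeated-split standard
    errors, and a synthetic reaction generator that emulates the statistical
    structure of literature hydrogenation data for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    uwot,
    randomForest,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
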