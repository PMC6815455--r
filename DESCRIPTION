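Package: qsarstack
Title: Multi-Subject Stacked Ensembles for QSAR Bioactivity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds comprehensive multi-subject ensembles for quantitative
    structure-activity relationship (QSAR) bioactivity classification.
    Bioassay compounds are represented four ways (PubChem, ECFP and MACCS
    molecular fingerprints, and character-level one-hot SMILES); thirteen
    first-level classifiers (random forest, linear SVM with Platt
    calibration, gradient boosting, feed-forward neural networks, and an
    end-to-end 1D-CNN followed by a GRU over the SMILES string) are combined
    by a second-level meta-learner trained on out-of-fold probabilities.
    Linear meta-learner weights are interpreted as model importances.
    Includes bootstrap bagging for class imbalance, random and
    Bemis-Murcko scaffold splits, ROC/MCC/F1 metrics with paired t-test and
    Pearson correlation helpers, a synthetic-assay generator with planted
    activity motifs, and packaged benchmark summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    randomForest,
    e1071,
    xgboost,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
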