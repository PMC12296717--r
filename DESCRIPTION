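Package: ChemoFusion
Title: Multi-Platform Data Fusion for Chemometric Origin Discrimination
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating the geographical origin of natural
    products from multi-platform metabolomics data. Four data blocks
    (LC-MS and GC-MS feature tables, 1H NMR and mid-infrared spectra) are
    preprocessed per platform (NMR chemical-shift referencing and fixed-width
    bucketing with water-region exclusion; Savitzky-Golay smoothing, vector
    normalization and uninformative-region removal for MIR), standardized,
    and combined by low-, mid- and high-level data fusion. Mid-level fusion
    supports PCA, PLS-DA, decision-tree and random-forest feature selection
    ahead of seven classifiers; high-level fusion merges per-block
    random-forest Gini importances under equal block weights. Models are
    compared by ROC/AUC, out-of-bag and train/test accuracy, precision,
    recall and F1; the top-ranked characteristic variables from the best
    model are screened and validated by unsupervised projection of an
    external sample set. A seeded synthetic multi-block generator with
    planted group-discriminative features supports benchmarking and
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    randomForest,
    rpart,
    e1071,
    class,
    mixOmics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
biocViews: Metabolomics, Classification, DimensionReduction, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
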