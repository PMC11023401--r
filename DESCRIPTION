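Package: scPFA
Title: Characteristic Feature Extraction for Single-Cell Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised extraction of small, characteristic gene sets from
    single-cell expression matrices. Redundant genes are removed by a
    principal feature analysis that tests all gene pairs for independence
    with an adaptively binned chi-square test and dissects the resulting
    dependence graph with minimal vertex cuts. Cells are then embedded
    (UMAP or t-SNE), grouped with density-based clustering (DBSCAN or
    HDBSCAN), and genes separating selected groups are filtered by
    chi-square association and ranked by mutual information. The selected
    set is validated with a multi-layer-perceptron classifier and explained
    through exact Shapley values and a pruned decision tree. A seeded
    synthetic-data generator with planted markers, redundancy and noise
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    uwot,
    Rtsne,
    nnet,
    rpart,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SingleCell, FeatureExtraction, Clustering, Classification,
    DimensionReduction
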