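Package: morphgcn
Title: Morphological Brain Connectivity Graphs and Graph Convolutional
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds subject-level morphological brain connectivity graphs
    from regional cortical-thickness distributions and classifies them with
    a compact graph convolutional network. Each cortical region is summarized
    by the first four moments of its vertex-wise thickness values (mean,
    standard deviation, skewness, kurtosis); region-to-region dissimilarities
    (Mahalanobis or taxicab) form a weighted adjacency that is thresholded at
    a fixed rejection quantile so every subject keeps the same graph density.
    Includes proportional and residual age/sex normalization fitted on
    healthy-control scans, patient-grouped stratified k-fold cross-validation,
    a full experiment grid over atlases, distances, thresholds and
    normalization modes, and a synthetic longitudinal cohort simulator for
    end-to-end testing without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
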