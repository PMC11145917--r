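Package: fosmapr
Title: Whole-Brain c-Fos Activity Mapping with a Hybrid 3D Swin Transformer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for mapping immediate-early-gene (c-Fos) neuronal
    activity in volumetric dual-channel fluorescence imaging of cleared mouse brain.
    Provides synthetic dual-channel phantom generation with exact ground truth,
    statistically thresholded spot-mask training data, a hybrid 3D shifted-window
    transformer segmentation network trained end to end in R, dual-channel
    false-positive filtering (autofluorescence, soma-size and intensity filters),
    hierarchical atlas-based quantification of cell counts, and group-comparison
    statistics (pooled t tests with Benjamini-Hochberg FDR, signed fold-change volcano
    classification, relative z-scores, coefficients of variation and Spearman
    correlation structure).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
SystemRequirements: C++17
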