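Package: benthoscan
Title: Automated Seafloor Classification from Towed-Camera Image Surveys
Version: 0.1.0
Authors@R:
    person("Benthoscan", "Developers", email = "benthoscan@example.org",
           role = c("aut", "cre"))
Description: An end-to-end workflow for classifying seafloor photographs from
    towed-camera transects into substrate classes. Covers laser-point
    detection and per-image scale estimation, illumination and color
    normalization (local z-score drop-off correction, contrast-limited
    adaptive histogram equalization, reference histogram matching),
    spatial-footprint standardization, texture/entropy feature extraction
    with a 2-D principal-component embedding, semi-automated label expansion
    by nearest-neighbor sampling, four training-set sampling strategies,
    k-means classification with silhouette-based model selection, a
    pluggable supervised classifier, agreement metrics (macro F1,
    Fowlkes-Mallows, Cohen's kappa), and georeferenced track export. A
    synthetic scene generator with full ground truth makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
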