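Package: ctcscope
Title: Label-Free Circulating Tumor Cell Detection from Bright-Field Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for label-free detection and counting of rare
    circulating tumor cells (CTCs) among white blood cells (WBCs) in
    bright-field microscopy images. Segments cells with brightness capping,
    Otsu edge detection, hole filling, morphological opening and marker-based
    watershed; transfers class labels from paired fluorescence channels; crops,
    normalizes and geometrically augments single-cell patches; trains a compact
    convolutional neural network classifier; and evaluates it with
    leakage-safe stratified five-fold cross-validation (confusion matrices,
    F-score, ROC/AUC, learning curves, t-SNE). Includes a synthetic paired
    bright-field/fluorescence image generator with ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
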