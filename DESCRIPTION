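Package: hipomapr
Title: Fixed-Size Whole-Slide Image Representations from Top-K Grad-CAM Patch Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts a whole-slide histopathology image, viewed as a bag of
    scored patches, into a fixed-size image-formatted representation: patches
    are ranked by a patch-level convolutional scorer, the top-K patches are
    summarised by a modified gradient-weighted class activation map whose
    flattened, descending-sorted rows are stacked into a K-by-(H*W) matrix,
    and a small convolutional network is trained on these matrices for
    slide-level classification, Cox proportional-hazards survival analysis,
    and survival regression. Includes tissue detection, grid patch
    extraction with tissue-fraction filtering, reference-based colour
    normalisation, a reproducible synthetic slide-cohort generator with
    proportional-hazards outcomes, and a compact CPU convolutional-network
    engine that exposes layer activations and their gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
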