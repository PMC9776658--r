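Package: fallstream
Title: Four-Stream 3D CNN Fall-Phase Classification from Fused Video Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vision-based human fall detection from short video windows.
    Sixteen consecutive grayscale frames are reduced by two levels of
    pairwise false-color image fusion to four RGB images that colorize
    inter-frame motion; a four-stream convolutional network (one stream
    per fused image, streams merged by concatenating global-average-pooled
    descriptors) classifies the window into one of four fall phases
    (standing, falling, fallen, other). Includes overlapping-window clip
    sampling, a three-fold cross-validated training and evaluation harness
    with confusion-matrix metrics, ROC curves and information density, a
    deterministic synthetic fall-video simulator for end-to-end testing
    without external data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    pROC,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
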