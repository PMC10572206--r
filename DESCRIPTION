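Package: grainsight
Title: Dense Small-Object Detection for Stored-Grain Insect Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-stage detection toolkit for dense, very small objects in
    stored-grain imagery: multi-scale anchor generation and matching, Soft-NMS
    (linear and Gaussian score decay), a position-sensitive prediction head with
    class-agnostic box regression, a compact fully convolutional backbone with
    Adam training, and a full evaluation protocol (IoU, precision/recall,
    all-point average precision, mAP, confusion matrices, ten-fold
    cross-validation). Includes Pascal VOC (labelImg dialect) annotation I/O,
    tiling and label-preserving augmentation, and a deterministic synthetic
    grain-scene generator so the whole pipeline can be exercised end to end
    without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    png,
    yaml,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
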