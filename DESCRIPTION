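Package: centrow
Title: Central Crop-Row Detection and Navigation-Line Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for vision-based in-row navigation in agricultural fields.
    Synthesizes crop-field scenes with exact three-class ground truth
    (background, vegetation, central crop row), binarizes vegetation with the
    Excess Green index or the CIE Lab a-channel plus Otsu thresholding, builds
    fixed-width navigation-line labels, trains a lightweight U-shaped
    segmentation network with optional depthwise-separable convolutions and
    atrous spatial pyramid pooling, extracts the navigation line by
    least-squares fitting of the largest connected component of the predicted
    row class, and scores results with pixel accuracy, mean IoU, angle error,
    line IoU and line accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
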