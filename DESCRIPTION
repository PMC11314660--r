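Package: ustherm
Title: Temporal-Informed Ultrasound Thermometry from B-Mode Texture Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive tissue temperature estimation during microwave
    hyperthermia from B-mode ultrasound image sequences. Extracts
    gray-level gradient co-occurrence matrix (GLGCM) texture features from
    a region of interest, decomposes the multichannel feature series into
    multi-period two-dimensional tensors via the FFT, and regresses
    temperature (25-65 degrees C regime) with a lightweight temporal
    network whose period-wise blocks use a dual-branch attention module
    (depthwise attention-convolution for local structure, scaled
    dot-product attention for global structure). Includes a synthetic
    heating-experiment generator for end-to-end validation, training and
    evaluation utilities, rendering of prediction curves and pseudocolor
    temperature maps, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    png,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
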