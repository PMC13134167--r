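Package: dcseg
Title: Dual-Consistency Semi-Supervised Segmentation for Histopathology Patches
Version: 0.1.0
Authors@R:
    person("R.", "Segworth", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-supervised semantic segmentation of histopathology image
    patches by dual consistency regularization: hierarchical consistency with
    per-pixel uncertainty rectification across multi-level decoder predictions,
    plus a coarse-fine grained consistency driven by a multi-scale convolution
    module that fuses shallow and deep decoder features. Includes a compact
    BLAS-backed U-Net training engine, a seeded generator of histology-like
    synthetic patches and whole-slide mosaics, segmentation metrics (IoU, Dice,
    accuracy, precision, recall), whole-slide tiling with background filtering
    and tumor-fraction labeling, prediction stitching, contour extraction at a
    fixed sampling interval, and polygon annotation export to ASAP-compatible
    XML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    withr,
    xml2,
    png,
    tiff,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
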