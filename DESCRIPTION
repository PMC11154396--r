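Package: stromatil
Title: Stroma-Restricted Tumor-Infiltrating Lymphocyte Scoring for Histopathology Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing and evaluating stroma-restricted tumor-infiltrating
    lymphocyte (TIL) scores from histopathology rasters. Provides tile-based
    preprocessing (256x256 cropping with zero padding, background filtering,
    eight-to-three tissue-class merging, COCO bounding-box rasterization),
    lymphocyte candidate extraction from probability maps with distance-based
    non-maximum suppression, per-slide TIL scoring restricted to the stromal
    compartment, and an evaluation stack (per-class Dice, greedy point matching,
    FROC curves and scores at fixed false-positive operating points, Pearson
    correlation against reference scores). A synthetic slide generator with full
    ground truth makes the complete pipeline testable end to end without any
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    withr,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
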