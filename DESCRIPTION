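Package: fruitseg
Title: Adaptive Color Thresholding for Fruit Detection in Field Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Dynamic adaptive thresholding for pixel-level fruit detection
    under highly variable illumination. Images are recursively split into
    illumination-homogeneous regions; per light level and per color
    dimension, binarization thresholds are learned from labeled images by
    an ROC sweep and applied at test time by linear interpolation across
    light levels, with mask intersections and morphological cleanup.
    Includes automatic parameter tuning (light-level cutoffs, stop
    splitting condition, classification-rule directions), pixel-level
    TPR/FPR/F-score evaluation, a cross-validation and sensitivity-analysis
    harness, and a synthetic labeled-scene generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
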