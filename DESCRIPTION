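Package: petalpix
Title: Floral Area Estimation from Images by Reference-Object Photogrammetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the projected floral area of flowering-plant images from
    the pixel ratio between segmented flowers and a planar reference object of
    known size (two-dimensional photogrammetry). Implements tiled (sliced)
    instance segmentation with mask merging in full-image coordinates, a
    pluggable segmentation backend contract with a deterministic HSV
    colour-threshold backend, confidence filtering, mask-level detection
    metrics (IoU, precision, recall, AP, mAP over IoU thresholds), and an
    evaluation toolkit for predicted-versus-measured area tables (bias,
    regression R2/RMSE, one-way ANOVA across flower colour, petal-display and
    capture-distance categories). A synthetic-scene generator renders
    flowering-plant scenes with exact ground-truth masks and areas so the whole
    pipeline can be validated without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
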