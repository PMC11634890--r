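Package: bandseg
Title: Shape-Prior Narrow-Band Boundary Segmentation for Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Boundary segmentation of noisy 2-D ultrasound images using a
    point distribution shape model, narrow-band normal-profile search with
    a neighbourhood gray-difference operator, and bidirectional
    exponentially weighted smoothing of the boundary-offset sequence with
    curvature-based outlier detection. Includes a speckle phantom
    simulator with exact ground truth and standard segmentation metrics
    (Dice, IoU, false-positive rate, mean/max absolute deviation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
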