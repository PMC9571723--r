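Package: aquacolor
Title: Water Color Identification for Aquaculture Pond Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Vision-based identification of aquaculture pond water color from
    fixed-camera images. Implements checkerboard-based color correction in CIE
    Lab space (fiducial marker localization, homography normalization and a
    least-squares 3x3 Lab correction matrix), extraction of water-only image
    patches scored by a Mamdani fuzzy inference system with centroid
    defuzzification, classification of patches into the 19 standard water-color
    codes, and majority voting for the representative pond color. Ships a
    synthetic pond-scene generator with exact ground truth so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    nnet,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
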