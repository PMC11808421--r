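Package: coloccrit
Title: Pearson Colocalisation Coefficients Under Explicit Pixel-Selection
    Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies colocalisation in two-channel fluorescence microscopy
    images with the Pearson's correlation coefficient (PCC) computed under
    three explicit pixel-selection criteria: all pixels (PCC_ALL), pixels
    above either channel threshold (PCC_OR), and pixels above both channel
    thresholds (PCC_AND).  Includes Otsu and Costes automatic thresholding,
    generators for synthetic benchmark image pairs (overlapping squares and
    Gaussian spot layouts), z-stack range analysis, cytofluorogram quadrant
    summaries, and randomisation nulls (channel rotation and block
    scrambling) with the associated t-tests and Hedges' g effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    MASS,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
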