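Package: splitgfr
Title: Automated Split Glomerular Filtration Rate from Dynamic Tc-99m DTPA
    Renal Scintigraphy
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for gamma-camera (Gates method) measurement of split
    glomerular filtration rate from dynamic Tc-99m DTPA renograms.
    Includes a physics-based phantom simulator with known ground-truth
    regions of interest and GFR, a compact U-Net segmentation model
    trained with a soft Dice loss to delineate kidney and perirenal
    background regions, morphological mask post-processing with an
    automatic pie-shaped background-ROI fallback, digitisation of
    structured report images (matched-filter character recognition and
    colour-keyed contour extraction), agreement statistics (Lin's
    concordance correlation, Bland-Altman limits of agreement, regression
    slope), a minimal dynamic nuclear-medicine DICOM reader/writer, and a
    command-line pipeline that ties the stages into a reproducible
    cross-validated experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
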