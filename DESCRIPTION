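Package: aslheight
Title: Label-Free Airway Surface Layer Height Quantification from
    Confocal Reflection XZ Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the height of the airway surface layer (ASL) on
    air-liquid interface epithelial cultures from confocal XZ scans.
    Reflection peaks arising at refractive-index interfaces
    (medium-transwell, transwell-cell, ASL-air) are located by Gaussian
    fitting of axial line profiles; ASL height is the peak-2 to peak-3
    separation minus the calcein-labelled cell-layer thickness obtained
    from half-maximum fluorescence boundaries. The conventional
    rhodamine-dextran fluorescence method is implemented alongside for
    cross-validation. Includes serpentine multi-position sampling plans,
    per-well summaries with coefficient of variation, subsampling
    stability analysis, group statistics with two-stage step-up false
    discovery rate adjustment, and a physics-based synthetic phantom
    generator (Fresnel interface amplitudes, axial point-spread blur,
    detector noise, lateral tilt) so the whole pipeline is testable
    against known ground truth without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
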