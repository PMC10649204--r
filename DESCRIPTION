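Package: nfspectral
Title: Multispectral Skin-Lesion Analysis for Neurofibromatosis Type 1 Screening
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for four-band multispectral skin imaging
    (405 nm autofluorescence through a 515 nm long-pass filter, and 526,
    663 and 964 nm diffuse reflectance): band-to-RGB-channel extraction,
    fiducial-marker based translational stabilization, threshold
    segmentation of lesions against perilesional skin, per-pixel
    chromophore-contrast p-prime mapping (log10 lesion/skin reflectance
    ratio), robust min-5 percent region statistics, and univariate
    sensitivity/specificity evaluation with Wilson confidence intervals.
    Includes a calibrated synthetic multispectral scene generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
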