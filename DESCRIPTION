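Package: pamclass
Title: Quantitative Melasma Classification from Photoacoustic Microscopy Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 3D photoacoustic microscopy (PAM) skin
    volumes aimed at quantitative melasma typing. Extracts the skin-surface
    profile from A-line signals, segments the epidermis and dermis at a
    boundary depth determined from vascular morphology on maximum amplitude
    projection (MAP) images, quantifies epidermal melanin (amplitude and
    maximum pigmentation depth) and dermal vessels (mean diameter, area
    density, diameter-density correlation), and applies a rule-based
    four-way classification (epidermal/mixed x M/M+V) comparing lesional
    against non-lesional skin. Includes a synthetic layered-skin phantom
    generator with known ground truth for validation, and readers/writers
    for multi-page TIFF and NIfTI volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
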