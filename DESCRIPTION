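Package: valveoptics
Title: Label-Free Optical Biomarkers of Early Aortic Valve Calcification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for label-free optical biomarkers of
    early calcific aortic valve disease in mouse models: per-pixel two-photon
    excited fluorescence (TPEF) autofluorescence ratio maps, quantitative
    polarized light imaging (QPLI) collagen metrics (phase retardation, axial
    fiber orientation, directional variance, collagen-positive pixel density),
    histological stain quantification (picrosirius-red hue binning, Alizarin
    Red S percent-area particle analysis), Teichholz echocardiographic volume
    and ejection-fraction formulas, ordinal immunohistochemistry score
    aggregation, and the group-comparison and correlation statistics layer.
    Ships a synthetic valve-phantom generator with known ground truth so the
    whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    car,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
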