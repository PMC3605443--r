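Package: hepafat
Title: Hepatic Steatosis Quantification from Dual-Echo MRI and Histology Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies liver fat from rapid in-phase/opposed-phase gradient-echo
    MRI via a T2*-corrected fat-sensitive parameter (alpha), and from colour
    histology sections via threshold/size/circularity particle morphometry of
    fat vacuoles. Includes a one-parameter nonlinear calibration linking alpha
    to the areal fat fraction, diagnostic-performance statistics (ROC curves
    with optimal cutoffs and exact binomial confidence intervals, log-scale
    Bland-Altman limits of agreement, log-scale prediction intervals), and
    synthetic-data generators (histology phantoms with known ground truth,
    a two-compartment spoiled-gradient-echo signal simulator, and cohort
    simulation) so the full pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
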