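Package: pcrfmri
Title: Principal Component Regression Decoding of Personalized Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates depression (BDI-II) and attachment-security (AAI
    coherence of mind) scores from task fMRI contrast maps using principal
    component regression with nested leave-one-out cross-validation.
    Provides first-level GLM analysis (canonical double-gamma HRF
    convolution, Gaussian spatial smoothing, voxelwise OLS, contrast
    estimation and inverse-variance fixed-effects combination across runs),
    fold-wise Z-thresholded region-of-interest selection, two-component PCA
    with a Moore-Penrose pseudoinverse model map, categorical diagnostic
    classification, and a synthetic-cohort simulator that plants a single
    contiguous activity cluster whose amplitudes depend linearly on the
    psychometric scores, so the full pipeline is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
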