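Package: segvol
Title: Residual U-Net Segmentation and Volumetric Measurement of Tumors in 3D MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for automatic segmentation and volumetric
    measurement of mass-enhancing tumors on 3D contrast-enhanced MRI. Provides
    a residual U-Net ('Res-UNet') trained with a combined Dice and
    cross-entropy objective, percentile-clamped z-score normalization,
    respacing and balanced patch sampling, training-time augmentation,
    sliding-window inference with rotation test-time augmentation and
    checkpoint ensembling, small-component post-filtering, radiomics-style
    shape features (maximum 3D diameter, mesh volume, covariance axis
    lengths), Otsu-based cystic/necrotic decomposition, T-stage
    classification, and DSC/IOU/ICC evaluation. A synthetic phantom module
    generates lesions with closed-form geometry so every stage can be
    validated against analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
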