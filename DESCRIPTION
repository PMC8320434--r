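Package: raunet
Title: Residual-Attention U-Net Cascade for Liver Tumor and Ablation Zone
    Segmentation in Contrast-Enhanced CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage, multi-scale residual-attention U-Net pipeline for
    segmenting the liver, liver tumors and thermal-ablation zones in
    multi-phase abdominal CT. Provides Hounsfield-unit preprocessing and
    isotropic resampling for NIfTI volumes, a compact CPU implementation of
    2D and 3D residual-attention U-Nets trained with the dice loss and Adam,
    cascaded inference (slice-wise liver segmentation, liver bounding box,
    overlapping multi-scale 3D patch tiling, stitching and scale merging),
    lesion-level detection and volumetric-agreement evaluation, and a seeded
    synthetic multi-phase CT phantom generator with exact ground-truth masks
    so the full pipeline can be exercised without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
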