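Package: kidneyvol
Title: Automated Parenchymal Kidney Volumetry for Dual-Station Body MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for measuring parenchymal kidney volume in
    dual-station abdominal water-fat MRI. Provides a seeded synthetic phantom
    generator with voxel-level ground truth, NIfTI input/output with spacing
    and origin metadata, 2.5D slice-stack preprocessing with elastic
    augmentation, a compact residual U-Net segmentation network trained with
    pixel-wise cross-entropy, fusion of overlapping imaging stations onto a
    common voxel grid, connected-component volumetry with left/right
    assignment by centre of mass, rule-based algorithmic quality control with
    two-stage percentile flagging, and a validation harness computing Dice,
    Jaccard, MAE, SMAPE, R-squared and Bland-Altman limits of agreement with
    subject-level cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
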