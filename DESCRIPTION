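Package: coroflow
Title: Coronary Centerline Pressure Prediction with Inverted Conditional Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale stack for learning coronary blood pressure along vessel
    centerlines from volumetric angiography-like images. Provides a synthetic
    hemodynamic phantom generator (vessel trees, rasterized volumes and a
    Poiseuille resistance-network pressure solver), coordinate-system handling
    (RAS/LPS conversion, rigid volume alignment, world-to-voxel transforms), a
    patch-based dataset builder pairing 28x28x28 image patches with centerline
    pressure labels, an inverted conditional diffusion (ICD) scalar regressor
    with a 3D convolutional conditioning encoder, a CNN-MLP baseline, training
    with decoupled-weight-decay Adam and Huber loss, and a case-wise evaluation
    suite (R2, Pearson correlation, RMSE, NRMSE) with fractional flow reserve
    flagging and error-map export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
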