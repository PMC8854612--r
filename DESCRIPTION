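Package: cranionet
Title: Automatic Cranial Implant Geometry from Defective Skull Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for deep-learning-based cranioplasty
    geometry design on binary voxel volumes. Generates synthetic
    upper-cranium shell phantoms, converts CT intensity volumes to binary
    cranial models by Hounsfield-unit thresholding, simulates six families
    of three-dimensional defect masks applied by Boolean subtraction,
    trains a compact skip-connected three-dimensional autoencoder with a
    dilated convolutional bottleneck (8,269 trainable parameters) to
    complete defective crania, extracts printable implant geometry by
    Boolean subtraction of the defective model from the completed one, and
    scores results with a volumetric error rate based on the 1-norm
    mismatch between ideal and generated implants.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
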