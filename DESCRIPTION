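Package: prtdose
Title: Progressive-Refinement Transformer Dose Prediction on Synthetic Pelvic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a progressive-refinement, windowed-attention
    image-to-dose model for volumetric-modulated arc therapy (VMAT) dose
    prediction, together with its preprocessing pipeline, a three-component
    fused training loss (mean-squared error, one-sided planning-target-volume
    voxel loss, pairwise rank loss), a deterministic CPU training loop, and a
    dosimetric evaluation suite (masked error metrics, dose-volume histogram
    statistics, gamma index, isodose overlap and surface-distance metrics,
    plan-criteria checks). A synthetic pelvic phantom generator provides
    desk-scale CT/structure/dose cases with the geometric structure the model
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
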