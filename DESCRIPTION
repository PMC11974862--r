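Package: elastoage
Title: Brain Age Modelling from Magnetic Resonance Elastography Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating brain age from voxelwise viscoelastic
    property maps (shear stiffness and damping ratio) derived from magnetic
    resonance elastography. Provides a synthetic phantom generator with
    age- and disease-dependent regional mechanics, conversion between
    complex shear modulus components and stiffness/damping maps, three
    brain-age model families (PCA with Gaussian-process regression, a
    supervised 3D residual convolutional network, and a self-supervised
    contrastive-regression encoder with adaptive age neighbourhoods and a
    ridge readout), occlusion-sensitivity saliency maps, Theil-Sen
    bias-corrected brain-age gaps, regional brain-age-gap profiles for
    disease cohorts, and profile-similarity screening of at-risk subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
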