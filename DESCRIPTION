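Package: radrobust
Title: Robustness of Radiomics Features to Inter-Observer Segmentation
    Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantifying how robust
    radiomics features are to inter-observer variability in manual 3D tumor
    segmentation. Provides a seeded synthetic phantom cohort generator (two
    segmentation-difficulty classes with simulated observers), IBSI-style
    pre-processing (normalization, isotropic resampling, fixed-bin-width
    discretization, stationary wavelet decomposition), shape, first-order
    and texture-matrix feature extraction (GLCM, GLRLM, GLSZM, NGTDM, GLDM),
    pairwise Dice similarity, near-zero-variance filtering, ICC(2,1)
    robustness classification, and easy-versus-challenging stratified
    comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
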