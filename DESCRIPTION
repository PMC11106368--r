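Package: lcseg
Title: Geometry-Based Locus Coeruleus Region Estimation from T1-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Landmark-driven construction of presumptive locus coeruleus (LC)
    region masks on T1-weighted brain MRI, together with the machinery to
    train and evaluate automatic LC localizers where the image itself offers
    no LC contrast. Provides NIfTI volume handling and world-space
    resampling; a seeded synthetic brainstem phantom with ground-truth LC
    spindles, enlarged presumptive masks, anatomical landmarks and a
    site/domain-shift knob; a spectral phase-image transform and intensity
    normalization for robustness across acquisition sites; an expected-label-
    value (ELV) style label-fusion localizer; a patch-based 3D U-Net trained
    with a Dice objective and overlap-averaged sliding-window inference; a
    fuzzy-atlas baseline propagated by diffeomorphic-demons registration;
    Dice/sensitivity evaluation with leave-one-out cross-validation; and a
    Bonferroni-corrected regional correlation scan with intracranial-volume
    adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
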