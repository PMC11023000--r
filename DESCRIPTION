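Package: brachynet
Title: Adversarial Dose Prediction and Plan-Approval Probability for HDR Brachytherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the probability that a cervical-cancer high-dose-rate
    brachytherapy (HDRBT) plan would be approved by a physician. A dose
    prediction network (DPN) maps a distance-histogram representation of the
    patient anatomy and the prescription dose to the four dosimetric measures
    that drive plan review (CTV D90% and bladder/rectum/sigmoid D2cc), and a
    plan-approval probability network (PPN) scores the total-course EQD2 of a
    plan against the same anatomy. The two networks are pre-trained separately
    and then trained jointly by an alternating least-squares adversarial
    scheme. Includes linear-quadratic EQD2 dose accounting with total-course
    extrapolation over external-beam and delivered fractions, exact Euclidean
    distance-transform anatomy featurization from binary structure masks and
    dwell positions, a synthetic cohort generator with a hidden physician
    policy for end-to-end validation, and an evaluation battery (ROC/AUC,
    perturbation-level sweeps, organ-at-risk scaling curves, anatomy
    consistency audit).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: 
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
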