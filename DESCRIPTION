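Package: flymotion
Title: Elementary Motion Detector Models for Naturalistic Visual Motion Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates fly photoreceptor responses to rigid translation of
    panoramic 1-D contrast images, and fits a hierarchy of elementary motion
    detector (EMD) architectures to the resulting naturalistic motion
    ensemble: the Hassenstein-Reichardt correlator (HRC), front-end
    nonlinearity variants, the weighted 4-quadrant (ON/OFF) model, and
    fourth-order polynomial nonlinearity models with two, four, or six input
    channels. Provides least-squares fitting with paired twofold
    cross-validation, optimal output scaling, lasso-based sparse predictor
    selection with ordinary least-squares refits, a synthetic image generator
    with controllable kurtosis and light-dark asymmetry, and a glider-stimulus
    benchmark that computes each model's predicted responses to binary
    stimuli with enforced 2-point and 3-point spatiotemporal correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
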