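Package: vacalibrate
Title: Calibration of Verbal-Autopsy Cause-Specific Mortality Fractions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Corrects cause-specific mortality fractions (CSMFs) estimated
    from computer-coded verbal autopsy (CCVA) predictions for algorithm
    misclassification.  Provides deterministic estimators (raw CSMFs,
    empirical misclassification matrices, the linear back-solve), a Bayesian
    latent-cause calibration model fitted by a data-augmented Gibbs sampler
    for single algorithms and multi-algorithm ensembles, WAIC-based
    comparison of calibrated and uncalibrated models, and a synthetic-data
    generator that emulates paired (reference-standard) and unpaired
    (surveillance) verbal-autopsy datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
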