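Package: mucran
Title: Multi-Confound Adversarial Regression Networks for 3D Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Trains three-dimensional convolutional classifiers on volumetric
    images (e.g. clinical brain MRI) while adversarially regressing out
    multiple categorical or binned confounding factors.  An encoder maps a
    volume to intermediary features and a regressor maps features to a padded
    one-hot array holding the disease label and every confound; a two-step
    adversarial update removes confound information from the features while
    keeping the label recoverable.  Includes the balanced batch scheduler used
    for heavily imbalanced clinical tables, deep-ensemble consensus
    uncertainty for out-of-distribution rejection, a synthetic confounded
    phantom generator, and evaluation utilities (confound-predictability
    AUROC, age-matched sampling, threshold-stratified accuracy reports).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
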