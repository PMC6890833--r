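Package: fcdiag
Title: Functional Connectivity Classification with a Tied-Weight
    Autoencoder and Similarity-Guided Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies subjects from resting-state fMRI region-of-interest
    (ROI) time series using pairwise Pearson functional connectivity.  The
    upper-triangle correlation vector is reduced to the most extreme (most
    positive and most negative) training-set average correlations, fed to a
    tied-weight autoencoder whose bottleneck drives a single-layer perceptron,
    and the two networks are trained jointly on the summed reconstruction and
    classification losses.  Training sets can be enlarged by SMOTE-style
    linear interpolation between a sample and one of its nearest same-class
    neighbours under the Extended Frobenius Norm (EROS) similarity over
    covariance eigenstructure.  Includes readers for ABIDE-style .1D time
    series and phenotype tables, a stratified cross-validation harness with
    strict train/test isolation, ROC/AUC metrics, and a synthetic two-class
    multivariate Gaussian generator with known discriminative region pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
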