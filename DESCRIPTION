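Package: dpca
Title: Demixed Principal Component Analysis for Neural Population Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Linear dimensionality reduction for multi-condition neural
    population recordings. Demixed principal component analysis (dPCA)
    decomposes trial-averaged firing rates into additive, pairwise
    uncorrelated marginalizations (condition-independent, stimulus,
    decision, and interaction terms) and then solves one regularized
    reduced-rank regression per marginalization, yielding decoder and
    encoder axes whose components are each tuned to a single task
    parameter while together capturing nearly as much variance as PCA.
    Includes preprocessing of spike trains (Gaussian smoothing,
    piecewise-linear time warping), re-balanced handling of unequal trial
    counts, cross-validated selection of the regularization strength,
    variance and signal-variance accounting, demixing indices, axis-angle
    and decoder-classification significance testing with shuffle nulls,
    a synthetic population generator with known ground truth, and
    implementations of the comparison methods (PCA per marginalization,
    targeted dimensionality reduction, factorial LDA, difference of
    covariances, and classical single-neuron ANOVA summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
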