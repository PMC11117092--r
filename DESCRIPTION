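Package: aglasso
Title: Adaptive Graphical Lasso for Partial Coherence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of frequency-domain functional connectivity as the
    partial coherence of band-limited multichannel neural signals, under a
    structural-network constraint.  Implements an adaptive graphical lasso
    for complex-valued (proper) Gaussian graphical models: an L1 penalty on
    the modulus of the spectral precision with two penalty levels, one on
    edges of a hypothesized binary network and one off it, selected by
    cross-validated deviance, followed by an unpenalized refit on the
    recovered support.  Includes baseline estimators (L2-regularized
    precision with percentile thresholding, bootstrap-thresholded coherence
    and imaginary coherence), a synthetic generative model for network
    recovery experiments, a quasi-physical MEG forward/inverse simulation of
    source leakage, and a band-pass multitaper front end for time series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
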