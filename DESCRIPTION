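Package: ordalt
Title: Alternative Parameterizations for Structural Equation Models of
    Ordinal Panel Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage estimation of structural equation models for binary
    and ordinal repeated measures via thresholds and polychoric
    correlations.  Implements the standard (delta/theta) identification of
    the auxiliary threshold layer together with the alternative
    parameterizations that free the underlying-variable means and
    variances over time (occasion-one anchoring and threshold anchoring),
    diagonally weighted least squares estimation with robust sandwich
    standard errors and a mean-and-variance-adjusted chi-square, linear
    growth, first-order autoregressive and autoregressive latent
    trajectory structural layers (univariate and multivariate), closed-form
    parameter-transformation maps between equivalent specifications, an
    empirical model-equivalence checker, threshold-invariance diagnostics,
    and a recursion-based simulator for ordinal panel data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
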