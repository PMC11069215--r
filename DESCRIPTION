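Package: transhaz
Title: Transformer-Based Discrete-Time Cause-Specific Hazard Models for
    Competing Risks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prediction of discrete-time cause-specific hazards under
    competing risks with a transformer encoder trained by minimizing the
    collapsed log-likelihood, together with a DeepHit-style feed-forward
    baseline. Includes a synthetic competing-risks cohort simulator with
    known ground-truth hazards (proportional, increasing and non-monotonic
    regimes with uniform censoring), evaluation metrics (hazard mean
    absolute error, integrated Brier score with inverse probability of
    censoring weights, time-dependent concordance, bootstrap confidence
    intervals, a Schoenfeld-residual proportional-hazards screen) and
    integrated-gradients feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
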