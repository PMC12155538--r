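Package: coxsusie
Title: Bayesian Variable Selection for Censored Time-to-Event Outcomes
    with the Sum of Single Effects Prior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fine-mapping of censored time-to-event (survival) outcomes by
    Bayesian variable selection. Combines the Cox proportional hazards
    partial likelihood with the sum-of-single-effects (SuSiE) prior,
    fitted by generalized iterative Bayesian stepwise selection (gIBSS).
    Per-variable evidence is summarized by a Laplace approximation to the
    single-variable Bayes factor, with Wakefield's asymptotic Bayes factor
    and a Gauss-Hermite quadrature gold standard available for comparison.
    Reports posterior inclusion probabilities and purity-filtered credible
    sets, and includes a simulator for correlated genotypes with censored
    survival outcomes plus calibration, power/FDR and credible-set
    evaluation metrics.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
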