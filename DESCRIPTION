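Package: qolsim
Title: Simulation-Based Comparison of Longitudinal Analysis Strategies for
    Health-Related Quality of Life
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo machinery for comparing three strategies for the
    longitudinal analysis of health-related quality of life (HRQoL) in
    randomized oncology trials: a linear mixed model on EORTC-style 0-100
    scores, time-to-deterioration survival endpoints analysed by
    Kaplan-Meier and log-rank, and a longitudinal partial credit model
    fitted to the raw polytomous item responses by marginal maximum
    likelihood with adaptive Gauss-Hermite quadrature. Includes a
    two-step generator for latent-trait driven item panels, an MNAR
    intermittent/monotone missing-data mechanism, and a replication
    harness estimating type I error and power of the treatment-arm by
    time interaction test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    lme4,
    survival,
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
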