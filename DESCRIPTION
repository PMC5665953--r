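Package: pecircuit
Title: Prediction-Error Circuit Models of Aversive Conditioning in Crickets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-level simulation and statistical analysis of aversive
    classical conditioning in crickets under the dopamine prediction-error
    circuit hypothesis. Implements a summed-error delta-rule circuit with two
    independently modifiable synapse populations (response and US-prediction
    pathways) and pharmacological gating, reference implementations of
    competing accounts of blocking (Rescorla-Wagner, attentional, comparator),
    machine-readable builders for compound-conditioning, blocking and
    auto-blocking protocols, a synthetic generator of two-odor preference-test
    data with per-animal random intercepts and a retention filter, and a
    binomial random-intercept mixed model fitted by adaptive Gauss-Hermite
    quadrature with Wald tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
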