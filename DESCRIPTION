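Package: micsoc
Title: Simulation and Bayesian Analysis of Desperation-Threshold Microsociety Games
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-round, multi-player economic microsociety games in
    which players choose to cooperate, steal, or work alone while a desperation
    threshold penalises rounds spent with resources below a critical level.
    Provides the four canonical study designs (threshold presence, punishment
    severity, and starting-inequality manipulations), synthetic-agent policies
    that generate session data with a known statistical structure, and the full
    analysis chain: standardized Bayesian random-intercept models fitted by
    Laplace approximation with Normal(0, 1) priors, Savage-Dickey Bayes factors
    with evidence categories, interaction decomposition into simple effects,
    and lagged set-level mediation of the inequality-stealing-trust pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
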