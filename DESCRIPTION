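Package: twostep
Title: Simulation, Behavioral Signatures, and Model Comparison for Two-Step Task Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying habitual control in sequential decision making with
    the two-step task. Simulates hybrid model-free/model-based Q-learning agents and
    model-based action-sequence (option chunking) agents on three task variants
    (binary rewards, graded drifting rewards, and a shared rare "red state" design),
    runs the one-trial-back behavioral signature analyses (Stage-1 stay regressions,
    Stage-2 choice and reaction-time sequence signatures with their trial-restriction
    filters, and a graded-versus-binned reward comparison), and fits five candidate
    models to trial-level choice data by maximum a posteriori estimation with Laplace
    approximations to the model evidence and random-effects Bayesian model selection
    (protected exceedance probabilities).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
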