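Package: metacontrol
Title: Metacontrol of Reinforcement-Learning Strategies in Sequential
    Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for studying metacontrol of
    decision-making strategies in a two-stage sequential decision task
    with reward-magnitude (stakes) and transition-stability
    manipulations.  Provides a generative hybrid model-free/model-based
    reinforcement-learning agent and the matching trial-wise likelihood,
    maximum a posteriori parameter estimation with multi-start
    optimization and AIC model-variant selection, baseline-corrected
    task-performance and metacontrol indices, Bayes factors for Pearson
    correlations under stretched beta priors and for paired t tests
    under JZS priors, a finite-population Monte-Carlo design analysis
    (Bayesian power analogue), and synthetic-cohort generation with
    Need-for-Cognition scores at a configurable population correlation
    to metacontrol.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
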