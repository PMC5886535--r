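Package: ssatbandit
Title: Stochastic Satisficing Models of Choice and Confidence in
    Two-Armed Bandits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and per-subject Bayesian fitting of learning and
    choice models for two-armed bandit tasks with continuous Gaussian
    payoffs. Implements reward-tracking, mean-variance expected utility,
    stochastic-satisficing (acceptability threshold) and power-utility
    model families, each with an optional drift of the unchosen option
    toward the threshold; trial-level simulation of two block-design
    experiments; adaptive-Metropolis posterior sampling with WAIC model
    comparison and confidence-regression goodness of fit; and the
    accompanying behavioural analyses (condition summaries, choice
    stability, critical correlation thresholds, reward-maximization and
    steady-state value-difference analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
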