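Package: metarl
Title: Hybrid Model-Based and Model-Free Reinforcement Learning for
    Two-Step Decision Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and model-based analysis of a two-step sequential
    decision-making task with deterministic, occasionally reversing
    transitions, drifting second-stage rewards, and trial-wise stakes cues.
    Implements the hybrid model-free/model-based reinforcement-learning
    model (SARSA(lambda) model-free learner, incremental transition
    learning with counterfactual updates, softmax choice rule with choice
    and response stickiness, condition-specific model-based weights),
    maximum a posteriori parameter estimation with parameter priors and
    random restarts, synthetic agent cohorts with planted group and
    condition effects, parameter recovery and posterior-predictive checks,
    and the downstream metacontrol analyses: baseline-corrected reward,
    mutual nearest-neighbour performance matching, revaluation-trial
    reaction-time preprocessing, and hierarchical Bayesian regression via
    'JAGS'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    coda,
    jsonlite,
    rjags,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
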