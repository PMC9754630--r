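Package: normbound
Title: Reward-Rate-Optimal Adaptive Decision Thresholds for Dynamic-Context
    Choice Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving, simulating and fitting normative decision
    rules in two-alternative forced-choice tasks whose reward or evidence
    quality changes within a single trial.  A dynamic-programming solver
    performs Bellman backward induction on a discretized belief (state
    likelihood) grid, co-optimizes the trial-averaged reward rate by root
    finding, and extracts time-varying (possibly infinite) decision
    thresholds, which are classified into qualitative dynamic motifs.
    Forward simulators implement noisy Bayesian, constant-threshold and
    urgency-gating observers under sensory and motor noise, and a
    Metropolis MCMC pipeline fits all three models to response-time
    distributions from the tokens task, with AICc, trial-wise RMSE and
    Kullback-Leibler model comparison.  Includes a synthetic-subject
    generator emulating the tokens-task data structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
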