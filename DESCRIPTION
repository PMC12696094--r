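Package: imaginerl
Title: Reinforcement Learning from Imagined Rewards in Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for model-based analysis of two-armed bandit tasks in which
    the outcome is an internally simulated (imagined) reward rather than an
    external payoff. Provides a five-model reinforcement-learning model space
    (Rescorla-Wagner, choice kernel, their combination, noisy
    win-stay-lose-shift, and a no-learning null model) with maximum-likelihood
    fitting, BIC and random-effects Bayesian model selection, parameter- and
    model-recovery studies, the accompanying behavioral statistics (acquired
    preference, one-tailed Wilcoxon signed-rank tests with effect sizes,
    baseline-corrected liking changes, robust skipped Spearman correlation),
    representational-similarity model matrices with Kendall tau scoring, and
    export of trial-wise prediction-error and value regressors for model-based
    fMRI. A synthetic-data module simulates full cohorts with the statistical
    structure the analyses assume, so the entire pipeline runs without any
    data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
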