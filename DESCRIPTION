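Package: crossoverbayes
Title: Bayesian and Frequentist Analysis of Replicated Crossover Recovery Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing replicated crossover trials of recovery
    interventions on the group and the individual level. Elicits informative
    normal priors for the intervention effect from meta-analytic evidence,
    estimates a Bayesian linear mixed model (random intercept and
    condition-by-subject random slope on pre-post change scores) by a
    self-contained Gibbs sampler with highest-posterior-density intervals and
    convergence diagnostics, and provides the matching frequentist comparators
    (REML mixed model with Satterthwaite degrees of freedom, per-subject
    linear-model intervals, hybrid intervals). A synthetic-data generator with
    known ground truth emulates the trial design so every stage is testable
    without the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    coda,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
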