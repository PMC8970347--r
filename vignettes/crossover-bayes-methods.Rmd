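---
title: "Bayesian analysis of replicated crossover recovery trials with informative priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian analysis of replicated crossover recovery trials with informative priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(crossoverbayes)
library(dplyr)
```

## The problem

Trials in elite sport face a small-n / small-effects conundrum: the athletes
available for a study are few, while the effects worth detecting are small.
Two remedies combine well. First, a *replicated crossover design*, in which
every subject receives both the intervention (here cold-water immersion, CWI,
after a fatiguing exercise bout) and the control condition more than once,
so that within-subject variability — and hence each subject's *individual
response* — becomes estimable. Second, *Bayesian estimation with an
informative prior*, which imports the evidence of larger sub-elite studies or
meta-analyses as a head start for the scarce elite data.

This package implements that analysis end to end for pre/post performance
tests: data validation and completeness filtering, prior elicitation, a
self-contained Gibbs sampler for the Bayesian mixed model with
highest-posterior-density intervals on the group and the individual level,
the standard frequentist comparators, and a synthetic-data generator with
known ground truth so that every stage can be exercised and calibrated
without access to any particular trial's raw data.

## Model

The analysis outcome is the change score
$d_{ij} = \text{post}_{ij} - \text{pre}_{ij}$ (seconds) for subject $i$ in
period $j$; for time outcomes a *negative* $d$ difference means benefit.
Both inference routes use the same linear mixed model

$$
d_{ij} = \beta_0 + \beta\, x_{ij} + b_i + c_i\, x_{ij} + \varepsilon_{ij},
\qquad
b_i \sim N(0, \tau_0^2),\quad
c_i \sim N(0, \tau_1^2),\quad
\varepsilon_{ij} \sim N(0, \sigma^2),
$$

with $x_{ij} = 1$ under the intervention and $0$ under control, so that
$\beta$ *is* the between-condition difference in pre-post change and
$\beta + c_i$ is subject $i$'s own effect. The $\pm\tfrac12$ coding
alternative was rejected for interpretability. Random intercept and slope
are modelled as independent; a covariance between them is not identifiable
in any useful way from 4 observations per subject and is deliberately
omitted. Modelling the measured times instead of their differences would be
preferable in principle but adds considerable complexity and is out of
scope.

## Prior elicitation

Meta-analytic evidence for CWI summarises to a beneficial effect of roughly
5% of baseline performance, with an adverse effect unlikely. `elicit_effect_prior()`
turns this into an outcome-scale normal prior by

* mean = cohort baseline mean × relative effect,
* sd = mean / `zero_sd_multiple`, with the default multiple 2 placing zero
  exactly two prior SDs below the expected benefit.

```{r}
elicit_effect_prior(0.978, 0.05, 2)   # 5 m sprint section
elicit_effect_prior(4.156, 0.05, 2)   # 30 m sprint
```

Priors are stored as *positive benefit magnitudes* with a `direction`
field; the sign flip onto the change scale (benefit = negative difference)
happens exactly once, inside `fit_bayes()`. Internal values are never
rounded; display rounding is half-to-even at 3 decimals.

Where transferability of the evidence is in doubt, `widen_prior()` inflates
the SD (mean unchanged, inflation ≥ 1), and `sensitivity_grid()` +
`run_sensitivity()` tabulate the posterior over a grid of shifted/widened
priors, base prior first. Remaining defaults: intercept $N(0, 100)$ (an SD,
consistent with the $N(\text{mean},\text{sd})$ notation used throughout),
and uniform$(0, 1000)$ on $\sigma^2$, $\tau_0^2$, $\tau_1^2$ — read
literally as priors on the *variances*. The bound for the residual variance
is stated evidence; applying the same bound to the random-effect variances
is this package's choice, made for consistency in the absence of a stated
value.

## Posterior computation

`fit_bayes()` runs a blocked Gibbs sampler written for exactly this model:

* $(\beta_0, b)$ and $(\beta, c)$ are updated as blocks: the fixed effect is
  drawn from its conditional with the corresponding random effects
  *marginalised* (subject means contribute precision
  $1/(\tau^2 + \sigma^2/n_i)$), then the random effects are drawn given it.
  The collapsed update matters: with single-site updates, $\beta$ and the
  $c_i$ lie on a ridge whenever $\sigma^2$ is small relative to $\tau_1^2$
  and the chain effectively stops moving.
* The variance components have scaled-inverse-$\chi^2$ conditionals
  truncated at the uniform prior's upper bound; they are drawn by inverse-CDF
  sampling of the corresponding truncated gamma in $1/\text{variance}$ (a
  numeric inversion on a log grid covers the shape-parameter edge case of
  two subjects). Draws are floored at $10^{-12}\,\mathrm{s}^2$ to keep all
  conditionals finite.
* A flat (improper) slope prior is the exact limit of omitting the
  prior-precision term; it is refused when no intervention observations are
  present, which is the one configuration that would leave the posterior
  improper.

Defaults follow the reference analysis where stated (5000 kept iterations)
and standard practice where not: warmup = iterations/2, discarded; thin 1;
4 chains with over-dispersed data-scale initial values. A fixed seed makes
draws bit-identical, and the sampler consumes data only through per-subject
sums, so results are invariant — to the bit — under permutation of input
rows.

`hpdi()` returns the shortest contiguous interval containing
$\lceil \text{level} \cdot n \rceil$ sorted draws (ties between equal-width
windows break to the earliest window after a stable sort), `group_interval()`
applies it to the $\beta$ draws and `individual_interval()` to
$\beta + c_i$; the individual posterior uses the posterior mean as its point
summary. `mcmc_diagnostics()` reports split R-hat and an
autocorrelation-based effective sample size per parameter (Geyer initial
monotone sequence), with constant (pinned) parameters reported as `NA`
rather than dividing by a zero within-chain variance; single-chain fits
warn and fall back to ESS only.

## Frequentist comparators

`fit_mixed_freq()` fits `change ~ condition + (1|subject) +
(1|subject:condition)` by REML with Satterthwaite degrees of freedom
(lme4/lmerTest), matching a "random effects: subject and
condition-by-subject" specification. With seven subjects, variance
components frequently hit the boundary; such singular fits proceed with the
boundary estimate and carry a `singular` flag. On fully degenerate
(zero-residual) data the Satterthwaite decoration itself can fail, in which
case the plain REML estimate is kept with conservative df
($n_\text{subjects}-1$) and the same flag.

On the individual level three interval types mirror the group comparison:
`per_subject_interval()` (an OLS two-group pooled-$t$ interval from that
subject's rows alone, requiring ≥ 2 replicates per condition),
`hybrid_interval()` (subject mean ± $t_{\mathrm{df}}$ × the *group*
mixed-model SE — equal width across subjects by construction), and the
Bayesian `individual_interval()`.

`effect_summary()` reports mean ± SD across subjects of per-subject
condition differences, averaging over replicates within subject first; a
`pairing = "replicate"` option pairs crossover replicate $r$ under
intervention with replicate $r$ under control instead.
`outcome_correlation()` correlates condition differences across the two
sprint outcomes, by default on the subject × replicate unit (14 points for
7 subjects) with per-subject aggregation as an option — the printed
correlation's unit is not stated, so both are computable.

## The synthetic generator and its calibration

`generate_trial()` emulates the study design: per subject a true baseline
per outcome, a subject intercept on the change scale, and individual
responses jointly normal across outcomes with correlation $\rho$; per period
the tabulated time is the arithmetic mean of 3 noisy timing trials, and the
post-test adds fatigue, the subject intercept, the (mean + individual)
treatment effect under intervention, and a period residual. One master seed
spawns an independent substream per subject.

`default_study_params()` pins the structure to the published cohort
summaries: 7 subjects, 2 replicates, baselines 0.978 ± 0.064 s (5 m) and
4.156 ± 0.193 s (30 m), treatment effects −0.060 s and +0.002 s. The
*decomposition* of the observed between-subject spread of estimated
differences (±0.060 and ±0.115 s) into true response heterogeneity versus
noise is not identifiable from cohort summaries; the defaults are a
calibration: `individual_response_sd` 0.04 (5 m) / 0.08 (30 m),
`trial_noise_sd` 0.03 / 0.05 and `residual_sd` 0.037 / 0.072, chosen so the
SD across subjects of estimated differences reproduces ≈ 0.060 / 0.115 s.
Control-condition fatigue means (0.05 / 0.01 s) and the latent response
correlation ($\rho = 0.7$) are likewise plausible calibrations, not
published values; note that at the replicate level the *observable*
correlation of condition differences is attenuated well below $\rho$ by
period noise. A period/sequence drift is deliberately absent from the model
(the design washes out between periods); the generator exposes no such term
either.

What passing tests on these data do and do not show: they verify the
estimators against known ground truth under the *assumed* generative model
(normal effects, homoscedastic noise, no carry-over). They cannot certify
the published dataset's exact numbers, timing-gate artefacts, or any real
violation of those assumptions.

```{r}
sim <- generate_trial(default_study_params(seed = 42))
count(sim$data, outcome, condition)
effect_summary(sim$data, "sprint5m")
```

## Problem sizes and verification

The package's own simulation studies use sizes chosen to keep the full
verification suite fast while leaving Monte-Carlo error well below every
tolerance asserted: conjugate-limit checks at 5000 kept draws (mean and SD
within 3 Monte-Carlo SEs of the closed form); cross-method agreement
averaged over 6 balanced datasets of 40 subjects; shrinkage ordering over 20
replicated 7-subject trials; coverage calibration with the truth drawn from
the informative prior over 200 replicated 7-subject trials at 2 × 1500
iterations (95% HPDIs must cover at the nominal rate within the 99%
binomial band); study-scale analyses keep 5000 iterations. Two systematic
effects surface in these comparisons and are properties of the methods, not
defects: boundary REML fits (flagged `singular`) have Satterthwaite df that
describe a collapsed model and can disagree with the flat-prior posterior on
a given dataset, and the uniform variance priors keep posterior mass away
from zero variance where REML plugs zero in, so Bayesian intervals run
slightly wide on such datasets. Agreement with the frequentist CI within a
few percent of interval width holds in tendency.

## Limitations

* The model analyses change scores, not measured values; floor/ceiling and
  regression-to-the-mean effects of the raw times are out of scope.
* Independent random intercept and slope; no carry-over or period terms.
* The uniform(0, 1000) bounds on all three variances treat the stated
  residual-variance prior as applying to the variance (not the SD), and
  extend it to the random effects for want of a stated choice.
* With two replicates per condition, per-subject confidence intervals have
  2 degrees of freedom and are fragile by construction; that fragility is
  the motivation for the hybrid and Bayesian individual intervals, not a
  bug to be engineered away.
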