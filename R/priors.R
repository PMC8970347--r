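#' Normal prior for an intervention effect on the time scale
#'
#' A prior is stored as a positive benefit magnitude in seconds together with
#' its direction: for sprint times a benefit *reduces* the outcome, so the
#' sign flip onto the pre-post-change model scale (benefit = negative change
#' difference) happens exactly once, inside the Bayesian model assembly.
#'
#' @param mean Expected benefit magnitude, seconds.
#' @param sd Prior standard deviation, seconds (> 0).  The second parameter of
#'   the `N(mean, sd)` notation is a standard deviation, not a variance.
#' @param direction `"benefit_reduces_outcome"` (time-like outcomes) or
#'   `"benefit_increases_outcome"`.
#' @return An object of class `normal_prior`.
#' @export
normal_prior <- function(mean, sd,
                         direction = c("benefit_reduces_outcome",
                                       "benefit_increases_outcome")) {
  direction <- match.arg(direction)
  if (!is.finite(mean)) abort("Prior mean must be finite.", class = "cob_domain_error")
  if (!is.finite(sd) || sd <= 0) {
    abort("Prior sd must be a positive finite number.", class = "cob_domain_error")
  }
  structure(list(mean = mean, sd = sd, direction = direction),
            class = "normal_prior")
}

#' @export
print.normal_prior <- function(x, ...) {
  cat(sprintf("Normal prior N(%s, %s)  [%s]\n",
              format(round(x$mean, 3)), format(round(x$sd, 3)), x$direction))
  invisible(x)
}

#' @export
format.normal_prior <- function(x, ...) {
  sprintf("N(%.3f, %.3f)", round(x$mean, 3), round(x$sd, 3))
}

#' Elicit an effect prior from meta-analytic evidence
#'
#' Converts a relative benefit (a fraction of baseline performance, as
#' summarised by a meta-analysis) into an outcome-scale normal prior.  The
#' prior mean is `baseline_mean * relative_effect`; its spread encodes how
#' unlikely an adverse effect is by placing zero `zero_sd_multiple` standard
#' deviations below the mean, i.e. `sd = mean / zero_sd_multiple`.
#'
#' Values are stored unrounded; [tidy()] and `format()` round half-to-even at
#' 3 decimals for display.
#'
#' @param baseline_mean Baseline performance (seconds, > 0), e.g. the cohort
#'   mean pre-test time.
#' @param relative_effect Expected relative benefit as a fraction (> 0), e.g.
#'   0.05 for "around 5% of initial performance".
#' @param zero_sd_multiple How many prior SDs separate the expected value from
#'   zero (> 0); 2 encodes "an adverse effect is unlikely".
#' @param direction Passed to [normal_prior()].
#' @return A `normal_prior`.
#' @export
#' @examples
#' elicit_effect_prior(0.978, 0.05, 2)  # N(0.049, 0.024) for 5 m sprint time
#' elicit_effect_prior(4.156, 0.05, 2)  # N(0.208, 0.104) for 30 m sprint time
elicit_effect_prior <- function(baseline_mean, relative_effect,
                                zero_sd_multiple = 2,
                                direction = "benefit_reduces_outcome") {
  for (v in c(baseline_mean = baseline_mean, relative_effect = relative_effect,
              zero_sd_multiple = zero_sd_multiple)) {
    if (!is.finite(v) || v <= 0) {
      abort("baseline_mean, relative_effect and zero_sd_multiple must be positive.",
            class = "cob_domain_error")
    }
  }
  m <- baseline_mean * relative_effect
  normal_prior(mean = m, sd = m / zero_sd_multiple, direction = direction)
}

#' Widen a prior to discount limited transferability
#'
#' Multiplies the prior SD by an inflation factor >= 1 while keeping the mean,
#' decreasing the prior's weight relative to the data.  Narrowing must go
#' through explicit re-elicitation, not through this function.
#'
#' @param prior A `normal_prior`.
#' @param inflation Multiplicative SD inflation, >= 1.
#' @return A `normal_prior`.
#' @export
widen_prior <- function(prior, inflation) {
  stopifnot(inherits(prior, "normal_prior"))
  if (!is.finite(inflation) || inflation < 1) {
    abort("inflation must be >= 1 (narrowing requires explicit re-elicitation).",
          class = "cob_domain_error")
  }
  normal_prior(prior$mean, prior$sd * inflation, prior$direction)
}

#' Grid of priors for sensitivity analysis
#'
#' Builds the Cartesian product of mean shifts and SD inflations around a base
#' prior, for re-running the analysis with a range of prior distributions.
#' The unmodified base prior is always the first element.
#'
#' @param prior Base `normal_prior`.
#' @param mean_shifts Numeric vector of additive mean shifts (seconds).
#' @param sd_inflations Numeric vector of multiplicative SD factors (> 0).
#' @return A list of `normal_prior` objects, base prior first.
#' @export
sensitivity_grid <- function(prior, mean_shifts = 0, sd_inflations = 1) {
  stopifnot(inherits(prior, "normal_prior"))
  if (length(mean_shifts) == 0 || length(sd_inflations) == 0) {
    abort("mean_shifts and sd_inflations must be non-empty.",
          class = "cob_domain_error")
  }
  if (any(!is.finite(sd_inflations)) || any(prior$sd * sd_inflations <= 0)) {
    abort("All resulting prior SDs must be positive.", class = "cob_domain_error")
  }
  grid <- tidyr::expand_grid(shift = mean_shifts, inflation = sd_inflations)
  out <- purrr::map2(grid$shift, grid$inflation, function(s, f) {
    normal_prior(prior$mean + s, prior$sd * f, prior$direction)
  })
  base <- purrr::detect_index(out, function(p) {
    isTRUE(all.equal(p$mean, prior$mean)) && isTRUE(all.equal(p$sd, prior$sd))
  })
  if (base > 1) out <- c(out[base], out[-base])
  if (base == 0) out <- c(list(prior), out)
  out
}

#' Full prior configuration for the Bayesian mixed model
#'
#' Bundles the slope (intervention-effect) prior with the intercept prior and
#' the uniform priors on the variance components.  Defaults: intercept
#' `N(0, 100)` (100 an SD), uniform(0, 1000) on the residual variance and on
#' both random-effect variances.  A flat (improper) slope prior is requested
#' with `slope_prior = "flat"`; it is admissible because the likelihood keeps
#' the posterior proper whenever intervention observations are present.
#'
#' @param slope_prior A `normal_prior` for the intervention effect, or the
#'   string `"flat"`.
#' @param intercept_prior A `normal_prior` for the model intercept (the mean
#'   control-condition change).  Its direction is ignored: the intercept prior
#'   lives directly on the change scale.
#' @param residual_variance_upper,random_intercept_variance_upper,random_slope_variance_upper
#'   Upper bounds of the uniform variance priors (s^2, > 0).
#' @return An object of class `prior_set`.
#' @export
prior_set <- function(slope_prior,
                      intercept_prior = normal_prior(0, 100),
                      residual_variance_upper = 1000,
                      random_intercept_variance_upper = 1000,
                      random_slope_variance_upper = 1000) {
  flat <- identical(slope_prior, "flat")
  if (!flat && !inherits(slope_prior, "normal_prior")) {
    abort("slope_prior must be a normal_prior or \"flat\".",
          class = "cob_domain_error")
  }
  if (!flat) {   # re-validate: rejects hand-built priors with illegal fields
    slope_prior <- normal_prior(slope_prior$mean, slope_prior$sd,
                                slope_prior$direction)
  }
  stopifnot(inherits(intercept_prior, "normal_prior"))
  uppers <- c(residual_variance_upper, random_intercept_variance_upper,
              random_slope_variance_upper)
  if (any(!is.finite(uppers)) || any(uppers <= 0)) {
    abort("Variance prior upper bounds must be positive.",
          class = "cob_domain_error")
  }
  structure(
    list(slope_prior = if (flat) "flat" else slope_prior,
         intercept_prior = intercept_prior,
         residual_variance_upper = residual_variance_upper,
         random_intercept_variance_upper = random_intercept_variance_upper,
         random_slope_variance_upper = random_slope_variance_upper),
    class = "prior_set"
  )
}

#' @export
print.prior_set <- function(x, ...) {
  slope <- if (identical(x$slope_prior, "flat")) "flat (improper)"
           else format(x$slope_prior)
  cat("Prior set:\n",
      "  slope (intervention effect): ", slope, "\n",
      "  intercept: ", format(x$intercept_prior), "\n",
      sprintf("  variances: residual U(0, %g), random intercept U(0, %g), random slope U(0, %g)\n",
              x$residual_variance_upper, x$random_intercept_variance_upper,
              x$random_slope_variance_upper),
      sep = "")
  invisible(x)
}

#' @rdname tidy.bayes_fit
#' @export
#' @method tidy normal_prior
tidy.normal_prior <- function(x, digits = 3, ...) {
  tibble::tibble(mean = round(x$mean, digits), sd = round(x$sd, digits),
                 direction = x$direction)
}
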