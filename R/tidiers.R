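#' Tidy posterior summaries of a Bayesian crossover fit
#'
#' One row per model parameter with posterior mean, SD and HPDI bounds,
#' broom-style.  `tidy.normal_prior` gives the display-rounded prior
#' parameters (half-to-even at `digits` decimals).
#'
#' @param x A `bayes_fit` (or `normal_prior`) object.
#' @param level HPDI level for the `conf.low`/`conf.high` columns.
#' @param digits Display rounding for priors.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method tidy bayes_fit
tidy.bayes_fit <- function(x, level = 0.95, ...) {
  pars <- setdiff(names(x$draws), c("chain", "iteration"))
  purrr::map_dfr(pars, function(p) {
    iv <- hpdi(x$draws[[p]], level)
    tibble::tibble(term = p, estimate = mean(x$draws[[p]]),
                   std.error = sd(x$draws[[p]]),
                   conf.low = iv$lower, conf.high = iv$upper)
  })
}

#' One-row model overview of a Bayesian crossover fit
#'
#' @param x A `bayes_fit` object.
#' @param ... Unused.
#' @return One-row tibble: outcome, draw counts, slope-prior description,
#'   worst split R-hat and smallest ESS across parameters.
#' @export
#' @method glance bayes_fit
glance.bayes_fit <- function(x, ...) {
  dg <- x$diagnostics %||% suppressWarnings(mcmc_diagnostics(x))
  tibble::tibble(
    outcome = x$outcome,
    nobs = nrow(x$changes),
    n_subjects = length(x$subjects),
    chains = x$config$chains,
    draws = nrow(x$draws),
    slope_prior = if (identical(x$priors$slope_prior, "flat")) "flat"
                  else format(x$priors$slope_prior),
    max_rhat = suppressWarnings(max(dg$rhat, na.rm = TRUE)),
    min_ess = suppressWarnings(min(dg$ess, na.rm = TRUE))
  )
}

#' Flat interval table of an analysis report
#'
#' @param x An `analysis_report`.
#' @param ... Unused.
#' @return Tibble combining group- and individual-level intervals with a
#'   `level_of_analysis` column.
#' @export
#' @method tidy analysis_report
tidy.analysis_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$group_results, level_of_analysis = "group",
                  subject = NA_character_),
    dplyr::mutate(x$individual_results, level_of_analysis = "individual")
  ) |>
    dplyr::select("outcome", "level_of_analysis", "subject", "approach",
                  "estimate", "lower", "upper", "level", "kind",
                  dplyr::any_of(c("p_value", "singular")))
}

#' One-row overview of an analysis report
#'
#' @param x An `analysis_report`.
#' @param ... Unused.
#' @return One-row tibble with subject counts, outcome count, correlation and
#'   diagnostics summary.
#' @export
#' @method glance analysis_report
glance.analysis_report <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(x$subject_order),
    n_outcomes = length(x$provenance$outcomes),
    n_excluded = length(unique(x$exclusions$subject)),
    correlation_r = x$correlation$r,
    correlation_p = x$correlation$p_value,
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    min_ess = suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE))
  )
}
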