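#' Highest posterior density interval of a sample
#'
#' The shortest contiguous interval of the sorted draws containing
#' `ceiling(level * n)` draws.  Unlike equal-tailed quantile intervals an HPDI
#' may be asymmetric around the mean.  Ties between equal-width windows are
#' broken to the earliest window after a stable sort.
#'
#' @param draws Numeric vector of posterior draws (>= 100).
#' @param level Coverage level in (0, 1), default 0.95.
#' @param kind Interval kind recorded in the result.
#' @return One-row tibble with columns `lower`, `upper`, `level`, `kind`.
#' @export
#' @examples
#' hpdi(rnorm(10000), 0.95)
hpdi <- function(draws, level = 0.95, kind = "hpdi") {
  draws <- as.numeric(draws)
  if (length(draws) < 100) {
    abort("At least 100 draws are required for a stable HPDI.",
          class = "cob_precision_error")
  }
  if (!is.finite(level) || level <= 0 || level >= 1) {
    abort("level must be in (0, 1).", class = "cob_domain_error")
  }
  s <- sort(draws, method = "radix")   # stable
  n <- length(s)
  m <- ceiling(level * n)
  widths <- s[m:n] - s[seq_len(n - m + 1)]
  i <- which.min(widths)               # earliest minimal window
  tibble::tibble(lower = s[i], upper = s[i + m - 1], level = level, kind = kind)
}

#' Group-level interval for the intervention effect
#'
#' HPDI of the posterior draws of the condition fixed effect, reported on the
#' pre-post-change scale where negative values mean benefit for time-like
#' outcomes.
#'
#' @param fit A [fit_bayes()] result.
#' @param level Coverage level.
#' @return One-row tibble `lower`, `upper`, `level`, `kind = "hpdi"`.
#' @export
group_interval <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "bayes_fit"))
  hpdi(fit$draws$beta_cwi, level)
}

#' Individual-level interval for one subject's intervention effect
#'
#' HPDI of the per-draw subject effect `beta_cwi + c_i`, i.e. the posterior of
#' that subject's own condition effect including its random-slope deviation.
#'
#' @param fit A [fit_bayes()] result.
#' @param subject Subject identifier present in the fitted data.
#' @param level Coverage level.
#' @return One-row tibble `lower`, `upper`, `level`, `kind = "hpdi"`.
#' @export
individual_interval <- function(fit, subject, level = 0.95) {
  stopifnot(inherits(fit, "bayes_fit"))
  if (!subject %in% fit$subjects) {
    abort(paste0("Unknown subject: ", subject), class = "cob_lookup_error")
  }
  hpdi(subject_effect_draws(fit, subject), level)
}

#' Posterior draws of one subject's intervention effect
#'
#' @inheritParams individual_interval
#' @return Numeric vector `beta_cwi + c_i`, one element per kept draw.
#' @export
subject_effect_draws <- function(fit, subject) {
  stopifnot(inherits(fit, "bayes_fit"))
  col <- paste0("c_", subject)
  if (!col %in% names(fit$draws)) {
    abort(paste0("Unknown subject: ", subject), class = "cob_lookup_error")
  }
  fit$draws$beta_cwi + fit$draws[[col]]
}
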