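#' Frequentist mixed-model estimate of the intervention effect
#'
#' Fits the comparator linear mixed model by REML on the pre-post change
#' scores: fixed effect condition, random effects for subject and the
#' condition-by-subject interaction (`change ~ condition + (1|subject) +
#' (1|subject:condition)`).  Inference for the fixed effect uses a t
#' distribution with Satterthwaite-approximated degrees of freedom.
#'
#' With very few subjects, variance components are frequently estimated on
#' the boundary (zero); such singular fits proceed with the boundary estimate
#' and are flagged, not errored.
#'
#' @param data Canonical trial data, complete for `outcome`.
#' @param outcome Outcome label.
#' @param level Confidence level, default 0.95.
#' @return One-row tibble with columns `estimate`, `se`, `df`, `lower`,
#'   `upper`, `p_value`, `level`, `kind = "ci"`, `singular`.
#' @export
#' @examples
#' sim <- generate_trial(default_study_params(seed = 1))
#' fit_mixed_freq(sim$data, "sprint5m")
fit_mixed_freq <- function(data, outcome, level = 0.95) {
  ch <- pre_post_changes(data, outcome)
  if (length(unique(ch$subject)) < 2) {
    abort("At least 2 subjects are required.", class = "cob_model_error")
  }
  ch$x <- as.numeric(ch$condition == "intervention")
  form <- change ~ x + (1 | subject) + (1 | subject:condition)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  quiet_fit <- function(expr) withCallingHandlers(
    expr, message = function(m) invokeRestart("muffleMessage"))
  # lmerTest decorates the fit for Satterthwaite df; on fully degenerate data
  # that decoration itself can fail, in which case the plain REML fit is kept
  fit <- tryCatch(
    quiet_fit(suppressWarnings(
      lmerTest::lmer(form, data = ch, REML = TRUE, control = ctrl))),
    error = function(e) quiet_fit(suppressWarnings(
      lme4::lmer(form, data = ch, REML = TRUE, control = ctrl))))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    warn("Variance component estimated on the boundary (singular REML fit).",
         class = "cob_singular_fit_warning")
  }
  co <- tryCatch(suppressWarnings(summary(fit)$coefficients["x", ]),
                 error = function(e) NULL)
  if (!is.null(co) && all(is.finite(co[c("Estimate", "Std. Error", "df")]))) {
    est <- unname(co["Estimate"]); se <- unname(co["Std. Error"])
    df <- unname(co["df"]); p <- unname(co["Pr(>|t|)"])
  } else {
    # degenerate (e.g. zero residual variance) fits break the Satterthwaite
    # machinery; keep the boundary REML estimate with conservative df
    est <- unname(lme4::fixef(fit)["x"])
    se <- tryCatch(suppressWarnings(
      unname(sqrt(diag(as.matrix(stats::vcov(fit)))["x"]))),
      error = function(e) NA_real_)
    if (!is.finite(se)) se <- 0
    df <- length(unique(ch$subject)) - 1
    p <- if (se > 0) 2 * pt(-abs(est / se), df) else as.numeric(est == 0)
    if (!singular) {
      warn("Degenerate mixed-model fit: falling back to boundary estimate with conservative df.",
           class = "cob_singular_fit_warning")
    }
    singular <- TRUE
  }
  tq <- qt(1 - (1 - level) / 2, df)
  tibble::tibble(estimate = est, se = se, df = df,
                 lower = est - tq * se, upper = est + tq * se,
                 p_value = p, level = level, kind = "ci", singular = singular)
}

#' Per-subject confidence interval from that subject's data alone
#'
#' Fits an ordinary linear model (change ~ condition) to one subject's rows
#' only: a two-group comparison with a pooled-variance t interval.  Requires
#' at least 2 replicates per condition, otherwise there are no residual
#' degrees of freedom.
#'
#' @param data Canonical trial data.
#' @param outcome Outcome label.
#' @param subject Subject identifier.
#' @param level Confidence level.
#' @return One-row tibble `estimate`, `se`, `df`, `lower`, `upper`, `level`,
#'   `kind = "ci"`.
#' @export
per_subject_interval <- function(data, outcome, subject, level = 0.95) {
  ch <- pre_post_changes(data, outcome)
  ch <- ch[ch$subject == subject, ]
  if (nrow(ch) == 0) {
    abort(paste0("Unknown subject: ", subject), class = "cob_lookup_error")
  }
  n1 <- sum(ch$condition == "intervention")
  n0 <- sum(ch$condition == "control")
  if (n1 < 2 || n0 < 2) {
    abort("At least 2 replicates per condition are needed for a per-subject interval.",
          class = "cob_insufficient_df_error")
  }
  ch$x <- as.numeric(ch$condition == "intervention")
  fit <- stats::lm(change ~ x, data = ch)
  est <- unname(stats::coef(fit)["x"])
  se <- unname(sqrt(diag(suppressWarnings(stats::vcov(fit))))["x"])
  df <- fit$df.residual
  tq <- qt(1 - (1 - level) / 2, df)
  tibble::tibble(estimate = est, se = se, df = df,
                 lower = est - tq * se, upper = est + tq * se,
                 level = level, kind = "ci")
}

# Per-subject mean condition difference (condition means of changes averaged
# over replicates, then intervention minus control).
subject_condition_difference <- function(changes) {
  changes |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(m = mean(.data$change), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "m") |>
    dplyr::transmute(.data$subject,
                     difference = .data$intervention - .data$control)
}

#' Hybrid individual interval: subject mean, group-based standard error
#'
#' Combines the subject's own mean condition difference with the group-based
#' standard error (and degrees of freedom) of the mixed-model fixed effect.
#' This keeps the interval width equal across subjects and avoids the
#' instability of per-subject variances at tiny n.
#'
#' @param data Canonical trial data.
#' @param outcome Outcome label.
#' @param subject Subject identifier.
#' @param group_fit A [fit_mixed_freq()] result for the same outcome.
#' @param level Confidence level.
#' @return One-row tibble `estimate`, `se`, `df`, `lower`, `upper`, `level`,
#'   `kind = "hybrid"`.
#' @export
hybrid_interval <- function(data, outcome, subject, group_fit, level = 0.95) {
  diffs <- subject_condition_difference(pre_post_changes(data, outcome))
  row <- diffs[diffs$subject == subject, ]
  if (nrow(row) == 0) {
    abort(paste0("Unknown subject: ", subject), class = "cob_lookup_error")
  }
  est <- row$difference
  tq <- qt(1 - (1 - level) / 2, group_fit$df)
  tibble::tibble(estimate = est, se = group_fit$se, df = group_fit$df,
                 lower = est - tq * group_fit$se,
                 upper = est + tq * group_fit$se,
                 level = level, kind = "hybrid")
}

#' Descriptive summary of the intervention effect
#'
#' Per subject, the difference of condition means of pre-post changes
#' (averaged over replicates first); summarised as mean and SD across
#' subjects.  With `pairing = "replicate"` the difference is instead taken
#' within each crossover replicate (pairing replicate r under intervention
#' with replicate r under control) before averaging.
#'
#' @param data Canonical trial data, complete for `outcome`.
#' @param outcome Outcome label.
#' @param pairing `"condition_means"` (default) or `"replicate"`.
#' @return One-row tibble `mean`, `sd`, `n_subjects`.
#' @export
effect_summary <- function(data, outcome,
                           pairing = c("condition_means", "replicate")) {
  pairing <- match.arg(pairing)
  ch <- pre_post_changes(data, outcome)
  diffs <- if (pairing == "condition_means") {
    subject_condition_difference(ch)
  } else {
    replicate_condition_differences(ch) |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(difference = mean(.data$difference), .groups = "drop")
  }
  tibble::tibble(mean = mean(diffs$difference), sd = sd(diffs$difference),
                 n_subjects = nrow(diffs))
}

# Per (subject, replicate) condition difference of changes.
replicate_condition_differences <- function(changes) {
  changes |>
    tidyr::pivot_wider(names_from = "condition", values_from = "change") |>
    dplyr::transmute(.data$subject, .data$replicate,
                     difference = .data$intervention - .data$control)
}

#' Correlation of individual responses across two outcomes
#'
#' Pearson correlation (with two-sided t-test) of the condition differences
#' in pre-post changes between two outcomes.  The default unit is the subject
#' x crossover-replicate pair (e.g. 14 points for 7 subjects in a two-fold
#' replicated crossover); per-subject aggregation is available via
#' `unit = "subject"`.
#'
#' @param data Canonical trial data complete for both outcomes.
#' @param outcome_a,outcome_b Outcome labels.
#' @param unit `"replicate"` (default) or `"subject"`.
#' @return One-row tibble `r`, `p_value`, `n`, `unit`.
#' @export
outcome_correlation <- function(data, outcome_a, outcome_b,
                                unit = c("replicate", "subject")) {
  unit <- match.arg(unit)
  get_diffs <- function(outcome) {
    ch <- pre_post_changes(data, outcome)
    if (unit == "replicate") {
      replicate_condition_differences(ch)
    } else {
      subject_condition_difference(ch)
    }
  }
  keys <- if (unit == "replicate") c("subject", "replicate") else "subject"
  merged <- dplyr::inner_join(get_diffs(outcome_a), get_diffs(outcome_b),
                              by = keys, suffix = c("_a", "_b"))
  if (nrow(merged) < 3) {
    abort("At least 3 paired units are needed for a correlation.",
          class = "cob_insufficient_data_error")
  }
  ct <- stats::cor.test(merged$difference_a, merged$difference_b,
                        method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(merged), unit = unit)
}

#' Baseline performance summary
#'
#' Mean and SD of pre-test times over all (subject, replicate, condition)
#' rows of one outcome — the cohort baseline that anchors relative-effect
#' prior elicitation.
#'
#' @param data Canonical trial data.
#' @param outcome Outcome label.
#' @return One-row tibble `mean`, `sd`, `n`.
#' @export
baseline_summary <- function(data, outcome) {
  data <- validate_trial_data(data, max_replicate = max(data$replicate, 2L))
  if (!outcome %in% data$outcome) {
    abort(paste0("Unknown outcome: ", outcome), class = "cob_lookup_error")
  }
  rows <- data[data$outcome == outcome, ]
  rows <- rows[order(rows$subject, rows$replicate, rows$condition), ]
  pre <- rows$pre_time
  tibble::tibble(mean = mean(pre), sd = sd(pre), n = length(pre))
}
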