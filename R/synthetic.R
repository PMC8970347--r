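#' Per-outcome parameters for the synthetic trial generator
#'
#' All values in seconds.  `fatigue_effect` is the mean pre-post change under
#' the control condition (positive = slower 24 h after the fatiguing
#' exercise); `treatment_effect` is the mean additional change under the
#' intervention (negative = benefit for time outcomes);
#' `individual_response_sd` is the SD of the condition-by-subject random
#' slopes, i.e. of the true individual responses.
#'
#' @param baseline_mean,baseline_sd Between-subject distribution of the true
#'   baseline sprint time.
#' @param fatigue_effect Mean control-condition change.
#' @param treatment_effect Mean intervention effect on the change scale.
#' @param random_intercept_sd SD of the subject random intercept (a subject's
#'   consistent deviation in change scores across all periods).
#' @param individual_response_sd SD of the true individual response.
#' @param residual_sd SD of the period-level residual on the change score.
#' @param trial_noise_sd SD of a single timing trial around the period's true
#'   time (each tabulated time is the mean of `trials_per_test` trials).
#' @return A list of class `outcome_params`.
#' @export
outcome_params <- function(baseline_mean, baseline_sd = 0,
                           fatigue_effect = 0, treatment_effect = 0,
                           random_intercept_sd = 0,
                           individual_response_sd = 0,
                           residual_sd = 0, trial_noise_sd = 0) {
  sds <- c(baseline_sd, random_intercept_sd, individual_response_sd,
           residual_sd, trial_noise_sd)
  if (baseline_mean <= 0 || any(!is.finite(sds)) || any(sds < 0)) {
    abort("baseline_mean must be > 0 and all SDs >= 0.",
          class = "cob_domain_error")
  }
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 fatigue_effect = fatigue_effect,
                 treatment_effect = treatment_effect,
                 random_intercept_sd = random_intercept_sd,
                 individual_response_sd = individual_response_sd,
                 residual_sd = residual_sd, trial_noise_sd = trial_noise_sd),
            class = "outcome_params")
}

#' Parameters of the synthetic replicated-crossover generator
#'
#' @param outcomes Named list of [outcome_params()], one per outcome.
#' @param n_subjects Number of subjects (default 7).
#' @param n_replicates Crossover replicates per condition (default 2).
#' @param response_correlation Correlation of the true individual responses
#'   across outcomes, in `[-1, 1]`.
#' @param trials_per_test Timing trials averaged into each tabulated time
#'   (default 3).
#' @param seed Default seed used by [generate_trial()].
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(outcomes, n_subjects = 7, n_replicates = 2,
                             response_correlation = 0, trials_per_test = 3,
                             seed = 1) {
  if (n_subjects < 1 || n_replicates < 1 || trials_per_test < 1) {
    abort("n_subjects, n_replicates and trials_per_test must be >= 1.",
          class = "cob_domain_error")
  }
  if (!is.finite(response_correlation) || abs(response_correlation) > 1) {
    abort("response_correlation must lie in [-1, 1].", class = "cob_domain_error")
  }
  if (!is.list(outcomes) || length(outcomes) == 0 ||
      is.null(names(outcomes)) || any(names(outcomes) == "") ||
      !all(vapply(outcomes, inherits, logical(1), "outcome_params"))) {
    abort("outcomes must be a named list of outcome_params().",
          class = "cob_domain_error")
  }
  structure(list(outcomes = outcomes,
                 n_subjects = as.integer(n_subjects),
                 n_replicates = as.integer(n_replicates),
                 response_correlation = response_correlation,
                 trials_per_test = as.integer(trials_per_test),
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

#' Generator parameters matching the study's printed summaries
#'
#' Seven subjects, two crossover replicates, two correlated sprint outcomes.
#' Baselines and effect means equal the published cohort summaries
#' (5 m: 0.978 s baseline, -0.060 s effect; 30 m: 4.156 s baseline, +0.002 s
#' effect); the noise components are calibrated so the SD across subjects of
#' estimated per-subject condition differences is about 0.060 s (5 m) and
#' 0.115 s (30 m).  That split between true response heterogeneity and noise
#' is a calibration choice: it is not identifiable from cohort summaries.
#'
#' @param seed Default seed for [generate_trial()].
#' @return A `synthetic_params` object.
#' @export
default_study_params <- function(seed = 1) {
  synthetic_params(
    outcomes = list(
      sprint5m = outcome_params(
        baseline_mean = 0.978, baseline_sd = 0.064,
        fatigue_effect = 0.05, treatment_effect = -0.060,
        random_intercept_sd = 0.02, individual_response_sd = 0.04,
        residual_sd = 0.037, trial_noise_sd = 0.03),
      sprint30m = outcome_params(
        baseline_mean = 4.156, baseline_sd = 0.193,
        fatigue_effect = 0.01, treatment_effect = 0.002,
        random_intercept_sd = 0.04, individual_response_sd = 0.08,
        residual_sd = 0.072, trial_noise_sd = 0.05)
    ),
    n_subjects = 7, n_replicates = 2,
    response_correlation = 0.7, trials_per_test = 3, seed = seed
  )
}

#' Generate a synthetic replicated-crossover trial with known ground truth
#'
#' For each subject, a true baseline time per outcome, a subject random
#' intercept on the change scale, and jointly normal individual responses
#' across outcomes (correlation `response_correlation`) are drawn from one
#' per-subject substream spawned deterministically from the master seed.
#' Each tabulated pre/post time is the arithmetic mean of `trials_per_test`
#' noisy timing trials; the post-test true time adds the fatigue effect, the
#' subject intercept, the (mean + individual) treatment effect under the
#' intervention, and a period-level residual.
#'
#' @param params A [synthetic_params()] object.
#' @param seed Seed overriding `params$seed`.
#' @return A list with `data` (canonical trial tibble, always valid and
#'   complete) and `truth` (list: `params`, `seed`, and a `subjects` tibble
#'   of every latent draw: baseline `mu`, intercept `b`, response `c` per
#'   subject and outcome).
#' @export
#' @examples
#' sim <- generate_trial(default_study_params(seed = 42))
#' dplyr::count(sim$data, outcome, condition)
generate_trial <- function(params, seed = NULL) {
  stopifnot(inherits(params, "synthetic_params"))
  seed <- as.integer(seed %||% params$seed)
  K <- length(params$outcomes)
  onames <- names(params$outcomes)
  rho <- params$response_correlation

  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1, params$n_subjects)
  subject_ids <- sprintf("S%02d", seq_len(params$n_subjects))

  # equicorrelated response structure across outcomes
  C <- matrix(rho, K, K); diag(C) <- 1
  L <- chol(C)

  rows <- vector("list", params$n_subjects)
  latents <- vector("list", params$n_subjects)
  for (i in seq_len(params$n_subjects)) {
    set.seed(subject_seeds[i])
    z <- as.numeric(rnorm(K) %*% L)
    sub_rows <- list(); r_idx <- 0L
    lat <- vector("list", K)
    for (k in seq_len(K)) {
      op <- params$outcomes[[k]]
      mu <- rnorm(1, op$baseline_mean, op$baseline_sd)
      b <- rnorm(1, 0, op$random_intercept_sd)
      ci <- z[k] * op$individual_response_sd
      lat[[k]] <- tibble::tibble(subject = subject_ids[i],
                                 outcome = onames[k],
                                 mu = mu, b = b, c = ci)
      for (cond in c("control", "intervention")) {
        xind <- as.numeric(cond == "intervention")
        for (rep in seq_len(params$n_replicates)) {
          pre <- mean(rnorm(params$trials_per_test, mu, op$trial_noise_sd))
          post_true <- mu + op$fatigue_effect + b +
            (op$treatment_effect + ci) * xind +
            rnorm(1, 0, op$residual_sd)
          post <- mean(rnorm(params$trials_per_test, post_true,
                             op$trial_noise_sd))
          r_idx <- r_idx + 1L
          sub_rows[[r_idx]] <- tibble::tibble(
            subject = subject_ids[i], replicate = rep, condition = cond,
            outcome = onames[k], pre_time = pre, post_time = post)
        }
      }
    }
    rows[[i]] <- dplyr::bind_rows(sub_rows)
    latents[[i]] <- dplyr::bind_rows(lat)
  }
  data <- dplyr::bind_rows(rows)
  if (any(data$pre_time <= 0) || any(data$post_time <= 0)) {
    abort("Generator parameters produced non-positive times; reduce the noise SDs relative to the baseline.",
          class = "cob_domain_error")
  }
  data <- validate_trial_data(data, max_replicate = params$n_replicates)
  list(data = data,
       truth = list(params = params, seed = seed,
                    subjects = dplyr::bind_rows(latents)))
}
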