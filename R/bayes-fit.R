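#' MCMC configuration
#'
#' @param iterations Post-warmup draws per chain (default 5000).
#' @param warmup Warmup iterations per chain, discarded; defaults to
#'   `iterations / 2`.
#' @param chains Number of chains (default 4, over-dispersed initial values).
#' @param seed Integer seed; identical (data, priors, config) give bit-identical
#'   draws.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 5000, warmup = NULL, chains = 4,
                        seed = 1, thin = 1) {
  if (is.null(warmup)) warmup <- ceiling(iterations / 2)
  stopifnot(iterations >= 1, warmup >= 0, chains >= 1, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 chains = as.integer(chains),
                 seed = as.integer(seed),
                 thin = as.integer(thin)),
            class = "mcmc_config")
}

# Draw from an inverse-gamma density x^-(a+1) exp(-b/x) truncated to
# (0, upper].  Via y = b/x, y ~ gamma(a, 1) truncated to y >= b/upper;
# integrable for any a once truncated.  Numeric-inversion fallback for a <= 0.
r_trunc_invgamma <- function(a, b, upper, floor_at = 1e-12) {
  if (b <= floor_at * 1e-3) return(floor_at)
  y_lo <- b / upper
  if (a > 0) {
    p_lo <- pgamma(y_lo, a)
    u <- runif(1, min(p_lo, 1 - 1e-12), 1)
    y <- qgamma(u, a)
  } else {
    lg <- seq(log(y_lo), log(y_lo + max(50, 20 * abs(a))), length.out = 2048)
    yg <- exp(lg)
    ld <- a * lg - yg            # log of y^(a-1) e^-y * y (log-grid Jacobian)
    w <- exp(ld - max(ld))
    cw <- cumsum(w)
    y <- yg[findInterval(runif(1) * cw[length(cw)], cw) + 1]
  }
  min(max(b / y, floor_at), upper)
}

#' Fit the Bayesian mixed model for pre-post changes by Gibbs sampling
#'
#' Samples the posterior of the linear mixed model
#' \deqn{d_{ij} = \beta_0 + \beta x_{ij} + b_i + c_i x_{ij} + \epsilon_{ij}}
#' where \eqn{d_{ij}} is the pre-post change of subject \eqn{i} in period
#' \eqn{j}, \eqn{x = 1} for the intervention and 0 for control,
#' \eqn{b_i \sim N(0, \tau_0^2)} are subject random intercepts,
#' \eqn{c_i \sim N(0, \tau_1^2)} are condition-by-subject random slopes
#' (the individual responses) and \eqn{\epsilon \sim N(0, \sigma^2)}.
#'
#' All location parameters have exact Gaussian full conditionals; the variance
#' components, under uniform(0, upper) priors, have scaled-inverse-chi-square
#' conditionals truncated at the upper bound, so the sampler is a pure Gibbs
#' scheme with no tuning.  A slope prior whose direction is
#' `benefit_reduces_outcome` enters the model as `N(-mean, sd)`: the prior is
#' elicited as a positive benefit magnitude while a benefit shows up as a
#' negative change difference.
#'
#' @param data Canonical trial data (see [read_trial_table()]), complete for
#'   `outcome`.
#' @param outcome Outcome label to analyse.
#' @param priors A [prior_set()].
#' @param config An [mcmc_config()].
#' @param pin Optional named list fixing variance components for reductions
#'   and oracle checks, e.g. `list(tau0_sq = 0, tau1_sq = 0, sigma_sq = 0.01)`.
#'   A tau pinned at 0 fixes the corresponding random effects at 0.
#' @param diagnostics Compute split R-hat / ESS after sampling and warn on
#'   apparent non-convergence (default TRUE).
#'
#' @return An object of class `bayes_fit`: a list with `draws` (tibble, one
#'   row per kept draw: `chain`, `iteration`, `beta0`, `beta_cwi`, `sigma_sq`,
#'   `tau0_sq`, `tau1_sq`, and per-subject columns `b_<id>`, `c_<id>`),
#'   `subjects`, `outcome`, `priors`, `config`, `pin`, `changes` (the change
#'   scores used) and `diagnostics`.
#' @export
#' @examples
#' sim <- generate_trial(default_study_params(seed = 1))
#' pr <- prior_set(elicit_effect_prior(0.978, 0.05, 2))
#' fit <- fit_bayes(sim$data, "sprint5m", pr,
#'                  mcmc_config(iterations = 500, chains = 2, seed = 1))
#' group_interval(fit)
fit_bayes <- function(data, outcome, priors, config = mcmc_config(),
                      pin = NULL, diagnostics = TRUE) {
  stopifnot(inherits(priors, "prior_set"), inherits(config, "mcmc_config"))
  ch <- pre_post_changes(data, outcome)
  subjects <- sort(unique(ch$subject))
  if (length(subjects) < 2) {
    abort("At least 2 subjects are required.", class = "cob_model_error")
  }
  if (any(table(ch$subject) < 2)) {
    abort("Every subject needs at least 2 observations.", class = "cob_model_error")
  }
  x <- as.numeric(ch$condition == "intervention")
  flat <- identical(priors$slope_prior, "flat")
  if (flat && sum(x) == 0) {
    abort("Flat slope prior with no intervention observations: improper posterior.",
          class = "cob_model_error")
  }
  d <- ch$change
  subj <- match(ch$subject, subjects)
  n <- length(d); S <- length(subjects)
  i1 <- which(x == 1)
  n1 <- length(i1)
  subj1 <- subj[i1]
  n_i <- tabulate(subj, S)
  n1_i <- tabulate(subj1, S)

  # prior terms on the model (change) scale
  int_mean <- priors$intercept_prior$mean
  int_prec <- 1 / priors$intercept_prior$sd^2
  if (!flat) {
    sp <- priors$slope_prior
    slope_mean <- if (sp$direction == "benefit_reduces_outcome") -sp$mean else sp$mean
    slope_prec <- 1 / sp$sd^2
  } else {
    slope_mean <- 0; slope_prec <- 0
  }

  pin <- pin %||% list()
  pin_sigma <- !is.null(pin$sigma_sq)
  pin_tau0 <- !is.null(pin$tau0_sq)
  pin_tau1 <- !is.null(pin$tau1_sq)
  if (pin_sigma && pin$sigma_sq <= 0) {
    abort("Pinned sigma_sq must be > 0.", class = "cob_domain_error")
  }
  floor_var <- 1e-12
  up_s <- priors$residual_variance_upper
  up_t0 <- priors$random_intercept_variance_upper
  up_t1 <- priors$random_slope_variance_upper

  n_keep <- config$iterations %/% config$thin
  par_names <- c("beta0", "beta_cwi", "sigma_sq", "tau0_sq", "tau1_sq",
                 paste0("b_", subjects), paste0("c_", subjects))
  all_draws <- vector("list", config$chains)

  set.seed(config$seed)
  d_sd <- max(sd(d), 1e-3)
  d_mean0 <- if (n1 < n) mean(d[x == 0]) else 0
  d_mean1 <- if (n1 > 0) mean(d[i1]) else 0

  for (chain in seq_len(config$chains)) {
    disp <- (chain - 1) / max(1, config$chains - 1) * 2 - 1  # in [-1, 1]
    beta0 <- d_mean0 + disp * 2 * d_sd + rnorm(1, 0, 0.1 * d_sd)
    beta <- (d_mean1 - d_mean0) - disp * 2 * d_sd + rnorm(1, 0, 0.1 * d_sd)
    b <- if (pin_tau0 && pin$tau0_sq == 0) numeric(S) else rnorm(S, 0, d_sd)
    cc <- if (pin_tau1 && pin$tau1_sq == 0) numeric(S) else rnorm(S, 0, d_sd)
    sigma_sq <- if (pin_sigma) pin$sigma_sq else
      min(max(var(d) * exp(disp), floor_var), up_s)
    tau0_sq <- if (pin_tau0) max(pin$tau0_sq, 0) else
      min(max(var(d) * exp(-disp), floor_var), up_t0)
    tau1_sq <- if (pin_tau1) max(pin$tau1_sq, 0) else
      min(max(var(d) * exp(disp / 2), floor_var), up_t1)

    keep <- matrix(NA_real_, n_keep, length(par_names))
    k <- 0L
    total <- config$warmup + config$iterations
    for (it in seq_len(total)) {
      tau0_eff <- if (pin_tau0 && pin$tau0_sq == 0) 0 else max(tau0_sq, floor_var)
      tau1_eff <- if (pin_tau1 && pin$tau1_sq == 0) 0 else max(tau1_sq, floor_var)

      # (beta0, b) block: beta0 from its conditional with b marginalised
      # (subject means q_i ~ N(beta0, tau0^2 + sigma^2/n_i)), then b | beta0.
      # Collapsing keeps the chain mobile when sigma^2 << tau^2 would
      # otherwise lock beta0 + b_i on a ridge.
      q <- d - beta * x - cc[subj] * x
      qbar <- rowsum(q, subj)[, 1] / n_i
      v0 <- tau0_eff + sigma_sq / n_i
      prec <- sum(1 / v0) + int_prec
      beta0 <- rnorm(1, (sum(qbar / v0) + int_mean * int_prec) / prec,
                     sqrt(1 / prec))
      if (tau0_eff > 0) {
        sums <- rowsum(q - beta0, subj)[, 1]
        prec_b <- n_i / sigma_sq + 1 / tau0_eff
        b <- rnorm(S, (sums / sigma_sq) / prec_b, sqrt(1 / prec_b))
      }

      # (beta_cwi, c) block, intervention rows only, c marginalised the same
      # way; prior-only when no intervention rows (flat+none was rejected).
      if (n1 > 0) {
        r1 <- d[i1] - beta0 - b[subj1]
        r1sum <- numeric(S)
        r1sum[sort(unique(subj1))] <- rowsum(r1, subj1)[, 1]
        has1 <- n1_i > 0
        v1 <- tau1_eff + sigma_sq / pmax(n1_i, 1L)
        prec <- sum(1 / v1[has1]) + slope_prec
        beta <- rnorm(1, (sum((r1sum[has1] / n1_i[has1]) / v1[has1]) +
                            slope_mean * slope_prec) / prec,
                      sqrt(1 / prec))
        if (tau1_eff > 0) {
          prec_c <- n1_i / sigma_sq + 1 / tau1_eff
          cc <- rnorm(S, ((r1sum - n1_i * beta) / sigma_sq) / prec_c,
                      sqrt(1 / prec_c))
        }
      } else {
        beta <- rnorm(1, slope_mean, sqrt(1 / slope_prec))
      }
      # variance components | .
      if (!pin_sigma) {
        resid <- d - beta0 - beta * x - b[subj] - cc[subj] * x
        sigma_sq <- r_trunc_invgamma(n / 2 - 1, sum(resid^2) / 2, up_s)
      }
      if (!pin_tau0) {
        tau0_sq <- r_trunc_invgamma(S / 2 - 1, sum(b^2) / 2, up_t0)
      }
      if (!pin_tau1) {
        tau1_sq <- r_trunc_invgamma(S / 2 - 1, sum(cc^2) / 2, up_t1)
      }
      post <- it - config$warmup
      if (post > 0 && post %% config$thin == 0) {
        k <- k + 1L
        keep[k, ] <- c(beta0, beta, sigma_sq, tau0_sq, tau1_sq, b, cc)
      }
    }
    colnames(keep) <- par_names
    all_draws[[chain]] <- tibble::as_tibble(keep) |>
      dplyr::mutate(chain = chain, iteration = seq_len(n_keep),
                    .before = 1)
  }

  fit <- structure(
    list(draws = dplyr::bind_rows(all_draws),
         subjects = subjects, outcome = outcome, priors = priors,
         config = config, pin = pin, changes = ch, diagnostics = NULL),
    class = "bayes_fit"
  )
  if (diagnostics) {
    fit$diagnostics <- mcmc_diagnostics(fit)
    bad <- dplyr::filter(fit$diagnostics, !is.na(.data$rhat),
                         .data$rhat > 1.05)
    if (nrow(bad) > 0) {
      warn(paste0("Possible non-convergence: split R-hat > 1.05 for ",
                  paste(bad$parameter, collapse = ", ")),
           class = "cob_convergence_warning")
    }
  }
  fit
}

#' @export
print.bayes_fit <- function(x, ...) {
  gi <- group_interval(x)
  cat(sprintf("Bayesian crossover mixed-model fit (outcome: %s)\n", x$outcome))
  cat(sprintf("  %d chains x %d kept draws (Gibbs), slope prior: %s\n",
              x$config$chains, x$config$iterations %/% x$config$thin,
              if (identical(x$priors$slope_prior, "flat")) "flat"
              else format(x$priors$slope_prior)))
  cat(sprintf("  intervention effect: %.4f s, %d%% HPDI [%.4f, %.4f]\n",
              mean(x$draws$beta_cwi), round(gi$level * 100),
              gi$lower, gi$upper))
  invisible(x)
}
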