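test_that("sampling is deterministic given data, priors and config", {
  sim <- generate_trial(default_study_params(seed = 2))
  cfg <- quick_mcmc(iterations = 300, seed = 9)
  f1 <- fit_bayes(sim$data, "sprint5m", prior_set(prior_5m()), cfg,
                  diagnostics = FALSE)
  f2 <- fit_bayes(sim$data, "sprint5m", prior_set(prior_5m()), cfg,
                  diagnostics = FALSE)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), 2 * 300)
  expect_true(all(f1$draws$sigma_sq > 0 & f1$draws$sigma_sq <= 1000))
  expect_true(all(f1$draws$tau1_sq > 0 & f1$draws$tau1_sq <= 1000))

  # permuting input rows changes nothing in the draws
  perm <- sim$data[rev(seq_len(nrow(sim$data))), ]
  f3 <- fit_bayes(perm, "sprint5m", prior_set(prior_5m()), cfg,
                  diagnostics = FALSE)
  expect_identical(f1$draws, f3$draws)
})

test_that("single-level reduction matches the conjugate closed form", {
  sim <- generate_trial(default_study_params(seed = 5))
  sigma_sq <- 0.002
  fit <- fit_bayes(sim$data, "sprint5m", prior_set("flat"),
                   quick_mcmc(iterations = 5000, seed = 2),
                   pin = list(tau0_sq = 0, tau1_sq = 0, sigma_sq = sigma_sq))
  ch <- pre_post_changes(sim$data, "sprint5m")
  oracle <- conjugate_mean_diff(ch$change[ch$condition == "intervention"],
                                ch$change[ch$condition == "control"], sigma_sq)
  dg <- fit$diagnostics
  mcse_mean <- dg$mcse[dg$parameter == "beta_cwi"]
  ess <- dg$ess[dg$parameter == "beta_cwi"]
  mcse_sd <- sd(fit$draws$beta_cwi) / sqrt(2 * (ess - 1))
  expect_lt(abs(mean(fit$draws$beta_cwi) - oracle$mean), 3 * mcse_mean)
  expect_lt(abs(sd(fit$draws$beta_cwi) - oracle$sd), 3 * mcse_sd)
  # pinned components stay put
  expect_true(all(fit$draws$sigma_sq == sigma_sq))
  expect_true(all(fit$draws[[paste0("b_", fit$subjects[1])]] == 0))
})

test_that("a near-degenerate slope prior pins the posterior at the signed prior mean", {
  sim <- generate_trial(default_study_params(seed = 4))
  fit <- fit_bayes(sim$data, "sprint5m",
                   prior_set(normal_prior(0.05, 1e-8)),
                   quick_mcmc(iterations = 1000, seed = 1),
                   diagnostics = FALSE)
  # benefit_reduces_outcome: prior mean +0.05 enters the model as -0.05
  expect_lt(abs(mean(fit$draws$beta_cwi) - (-0.05)), 1e-4)
})

test_that("the sampler recovers a known treatment effect at n_subjects = 40", {
  p <- default_study_params(seed = 13)
  p$n_subjects <- 40L
  sim <- generate_trial(p)
  fit <- fit_bayes(sim$data, "sprint5m", prior_set(prior_5m()),
                   quick_mcmc(iterations = 2000, seed = 8),
                   diagnostics = FALSE)
  post_mean <- mean(fit$draws$beta_cwi)
  post_sd <- sd(fit$draws$beta_cwi)
  expect_lt(abs(post_mean - (-0.06)), 3 * post_sd)
})

test_that("flat slope prior without intervention data is rejected as improper", {
  sim <- generate_trial(default_study_params(seed = 1))
  ctrl_only <- dplyr::filter(sim$data, condition == "control")
  expect_error(fit_bayes(ctrl_only, "sprint5m", prior_set("flat"),
                         quick_mcmc(iterations = 200)),
               class = "cob_model_error")
  one_subj <- dplyr::filter(sim$data, subject == "S01")
  expect_error(fit_bayes(one_subj, "sprint5m", prior_set("flat"),
                         quick_mcmc(iterations = 200)),
               class = "cob_model_error")
})

test_that("individual intervals collapse to the group interval without slope heterogeneity", {
  sim <- generate_trial(default_study_params(seed = 6))
  fit <- fit_bayes(sim$data, "sprint5m", prior_set(prior_5m()),
                   quick_mcmc(iterations = 1000, seed = 3),
                   pin = list(tau1_sq = 0), diagnostics = FALSE)
  gi <- group_interval(fit)
  for (s in fit$subjects[c(1, 4, 7)]) {
    expect_equal(individual_interval(fit, s), gi)
  }
  expect_error(individual_interval(fit, "nobody"), class = "cob_lookup_error")
})

test_that("an extreme responder is shrunk between its raw mean and the group mean", {
  # subject E responds at +0.10 while the prior expects -0.05 and the other
  # subjects respond around -0.05
  set.seed(21)
  subjects <- c(sprintf("P%d", 1:7), "E")
  effects <- c(rnorm(7, -0.05, 0.01), 0.10)
  ch <- grid_changes(subjects) |>
    dplyr::mutate(change = ifelse(condition == "intervention",
                                  effects[match(subject, subjects)], 0) +
             rnorm(dplyr::n(), 0, 0.01))
  dat <- toy_trial(ch)
  fit <- fit_bayes(dat, "sprint5m", prior_set(normal_prior(0.05, 0.024)),
                   quick_mcmc(iterations = 3000, seed = 5),
                   diagnostics = FALSE)
  raw <- subject_effect_raw <- mean(ch$change[ch$subject == "E" &
                                                ch$condition == "intervention"]) -
    mean(ch$change[ch$subject == "E" & ch$condition == "control"])
  post_e <- mean(subject_effect_draws(fit, "E"))
  group_mean <- mean(fit$draws$beta_cwi)
  expect_gt(raw, group_mean)               # sanity on the construction
  expect_lt(post_e, raw)                   # pulled off the raw mean ...
  expect_gt(post_e, group_mean)            # ... but not past the group mean
})

test_that("more replicates pull an individual posterior towards its raw mean", {
  post_dist <- vapply(c(2L, 4L, 8L), function(reps) {
    set.seed(31)
    subjects <- c(sprintf("P%d", 1:7), "E")
    ch <- grid_changes(subjects, n_replicates = reps) |>
      dplyr::mutate(change = ifelse(condition == "intervention",
                                    ifelse(subject == "E", 0.10, -0.05), 0) +
               rnorm(dplyr::n(), 0, 0.04))
    dat <- toy_trial(ch)
    fit <- fit_bayes(dat, "sprint5m", prior_set(normal_prior(0.05, 0.024)),
                     quick_mcmc(iterations = 3000, seed = 5),
                     diagnostics = FALSE)
    raw <- mean(ch$change[ch$subject == "E" & ch$condition == "intervention"]) -
      mean(ch$change[ch$subject == "E" & ch$condition == "control"])
    abs(mean(subject_effect_draws(fit, "E")) - raw)
  }, numeric(1))
  expect_true(all(diff(post_dist) < 0))
})

test_that("diagnostics flag unmixed chains and tolerate constant parameters", {
  # two deterministic, far-apart chains built directly
  n <- 50
  draws <- tibble::tibble(
    chain = rep(1:2, each = n), iteration = rep(seq_len(n), 2),
    beta_cwi = rep(c(-1000, 1000), each = n) + rep(sin(seq_len(n)), 2),
    const = 0.5)
  fake <- structure(list(draws = draws,
                         config = mcmc_config(iterations = n, chains = 2),
                         changes = tibble::tibble(x = 1), subjects = "A"),
                    class = "bayes_fit")
  dg <- mcmc_diagnostics(fake)
  expect_false(dg$pass[dg$parameter == "beta_cwi"])
  expect_gt(dg$rhat[dg$parameter == "beta_cwi"], 1.05)
  # constant parameter: no division blow-up, reported NA but passing
  expect_true(is.na(dg$rhat[dg$parameter == "const"]))
  expect_true(dg$pass[dg$parameter == "const"])

  # a well-mixed fit passes cleanly
  sim <- generate_trial(default_study_params(seed = 3))
  fit <- fit_bayes(sim$data, "sprint5m", prior_set(prior_5m()),
                   quick_mcmc(iterations = 2000, seed = 2))
  expect_true(all(fit$diagnostics$rhat < 1.05, na.rm = TRUE))

  # single chain: ESS only, with a warning
  f1 <- fit_bayes(sim$data, "sprint5m", prior_set(prior_5m()),
                  mcmc_config(iterations = 500, chains = 1, seed = 2),
                  diagnostics = FALSE)
  expect_warning(dg1 <- mcmc_diagnostics(f1), class = "cob_diagnostics_warning")
  expect_true(all(is.na(dg1$rhat)))
  expect_true(any(is.finite(dg1$ess)))
})

test_that("broom methods summarise fits tidily", {
  sim <- generate_trial(default_study_params(seed = 2))
  fit <- fit_bayes(sim$data, "sprint5m", prior_set(prior_5m()),
                   quick_mcmc(iterations = 500, seed = 2))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in% names(td)))
  expect_true("beta_cwi" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 7)
  expect_equal(gl$draws, 1000)
  expect_s3_class(autoplot(fit), "ggplot")
})
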