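test_that("REML fixed effect equals the balanced-design closed form", {
  set.seed(14)
  subjects <- sprintf("P%d", 1:9)
  ch <- grid_changes(subjects) |>
    dplyr::mutate(change = rnorm(dplyr::n(), 0.02, 0.05) +
             ifelse(condition == "intervention", -0.06, 0))
  dat <- toy_trial(ch)
  fit <- suppressWarnings(fit_mixed_freq(dat, "sprint5m"))
  oracle <- ch |>
    dplyr::group_by(subject, condition) |>
    dplyr::summarise(m = mean(change), .groups = "drop") |>
    tidyr::pivot_wider(names_from = condition, values_from = m) |>
    dplyr::summarise(d = mean(intervention - control))
  expect_equal(fit$estimate, oracle$d, tolerance = 1e-6)
  # effect_summary mean agrees with the mixed-model estimate on balanced data
  es <- effect_summary(dat, "sprint5m")
  expect_equal(es$mean, fit$estimate, tolerance = 1e-6)
})

test_that("zero-noise data return the true effect exactly, flagged singular", {
  ch <- grid_changes(sprintf("P%d", 1:5)) |>
    dplyr::mutate(change = ifelse(condition == "intervention", -0.06, 0))
  dat <- toy_trial(ch)
  expect_warning(fit <- fit_mixed_freq(dat, "sprint5m"),
                 class = "cob_singular_fit_warning")
  expect_equal(fit$estimate, -0.06, tolerance = 1e-10)
  expect_true(fit$singular)
})

test_that("per-subject intervals equal the pooled two-sample t computation", {
  ch <- tibble::tibble(
    subject = "A", replicate = c(1, 2, 1, 2),
    condition = c("intervention", "intervention", "control", "control"),
    change = c(-0.10, -0.06, 0.00, 0.02))
  dat <- toy_trial(ch)
  iv <- per_subject_interval(dat, "sprint5m", "A")
  # hand-computed: est -0.09, pooled sd^2 = 0.0005, df = 2, t = 4.3027
  se <- sqrt(0.0005 * (1 / 2 + 1 / 2))
  expect_equal(iv$estimate, -0.09)
  expect_equal(iv$df, 2)
  expect_equal(iv$lower, -0.09 - 4.302653 * se, tolerance = 1e-6)
  expect_equal(iv$upper, -0.09 + 4.302653 * se, tolerance = 1e-6)

  # property: agreement with an independent brute-force t computation
  set.seed(8)
  for (i in 1:25) {
    n <- sample(2:5, 1)
    d1 <- rnorm(n, -0.05, 0.04); d0 <- rnorm(n, 0, 0.04)
    chr <- tibble::tibble(
      subject = "Z",
      replicate = c(seq_len(n), seq_len(n)),
      condition = rep(c("intervention", "control"), each = n),
      change = c(d1, d0))
    ivr <- per_subject_interval(toy_trial(chr), "sprint5m", "Z",
                                level = 0.9)
    sp2 <- (sum((d1 - mean(d1))^2) + sum((d0 - mean(d0))^2)) / (2 * n - 2)
    se_r <- sqrt(sp2 * 2 / n)
    tq <- qt(0.95, 2 * n - 2)
    expect_equal(ivr$estimate, mean(d1) - mean(d0), tolerance = 1e-10)
    expect_equal(ivr$lower, mean(d1) - mean(d0) - tq * se_r, tolerance = 1e-8)
    expect_equal(ivr$upper, mean(d1) - mean(d0) + tq * se_r, tolerance = 1e-8)
  }
})

test_that("degenerate and underdetermined per-subject cases behave as specified", {
  ch0 <- tibble::tibble(
    subject = "A", replicate = c(1, 2, 1, 2),
    condition = c("intervention", "intervention", "control", "control"),
    change = c(-0.08, -0.08, 0.01, 0.01))
  iv <- per_subject_interval(toy_trial(ch0), "sprint5m", "A")
  expect_equal(iv$lower, -0.09)
  expect_equal(iv$upper, -0.09)

  ch1 <- dplyr::filter(ch0, replicate == 1)
  expect_error(per_subject_interval(toy_trial(ch1), "sprint5m", "A"),
               class = "cob_insufficient_df_error")
})

test_that("hybrid intervals use the subject mean with the group se and df", {
  sim <- generate_trial(default_study_params(seed = 9))
  fit <- suppressWarnings(fit_mixed_freq(sim$data, "sprint5m"))
  group_fit <- tibble::tibble(estimate = fit$estimate, se = 0.02, df = 6)
  hy <- hybrid_interval(sim$data, "sprint5m", "S03", group_fit)
  diffs <- effect_summary(sim$data, "sprint5m")  # sanity: complete data
  expect_equal(hy$upper - hy$lower, 2 * 2.446912 * 0.02, tolerance = 1e-6)

  # worked t-quantile example: mean -0.09, se 0.02, df 6
  ch <- grid_changes(c("A", "B")) |>
    dplyr::mutate(change = ifelse(condition == "intervention", -0.09, 0))
  hy2 <- hybrid_interval(toy_trial(ch), "sprint5m", "A",
                         tibble::tibble(se = 0.02, df = 6))
  expect_equal(hy2$estimate, -0.09)
  expect_equal(hy2$lower, -0.09 - 2.446912 * 0.02, tolerance = 1e-5)
  expect_equal(hy2$upper, -0.09 + 2.446912 * 0.02, tolerance = 1e-5)
  # identical data -> identical hybrid interval for both subjects
  expect_equal(hybrid_interval(toy_trial(ch), "sprint5m", "B",
                               tibble::tibble(se = 0.02, df = 6)), hy2)
})

test_that("intervals shrink monotonically as the level decreases", {
  sim <- generate_trial(default_study_params(seed = 10))
  widths <- function(f) vapply(c(0.99, 0.95, 0.8, 0.5), function(lv) {
    iv <- f(lv); iv$upper - iv$lower
  }, numeric(1))
  w1 <- widths(function(lv) suppressWarnings(
    fit_mixed_freq(sim$data, "sprint5m", level = lv)))
  w2 <- widths(function(lv) per_subject_interval(sim$data, "sprint5m", "S02",
                                                 level = lv))
  fit <- fit_bayes(sim$data, "sprint5m", prior_set(prior_5m()),
                   quick_mcmc(iterations = 2000, seed = 4), diagnostics = FALSE)
  w3 <- widths(function(lv) group_interval(fit, lv))
  expect_true(all(diff(w1) < 0))
  expect_true(all(diff(w2) < 0))
  expect_true(all(diff(w3) < 0))
})

test_that("effect summaries aggregate per-subject condition differences", {
  ch <- grid_changes(c("A", "B", "C")) |>
    dplyr::mutate(change = ifelse(condition == "intervention",
                                  c(A = -0.02, B = -0.06, C = -0.10)[subject], 0))
  es <- effect_summary(toy_trial(ch), "sprint5m")
  expect_equal(es$mean, -0.06)
  expect_equal(es$sd, 0.04)

  # every subject at exactly delta -> (delta, 0)
  chd <- grid_changes(c("A", "B")) |>
    dplyr::mutate(change = ifelse(condition == "intervention", -0.05, 0))
  esd <- effect_summary(toy_trial(chd), "sprint5m")
  expect_equal(esd$mean, -0.05)
  expect_equal(esd$sd, 0)

  # replicate pairing agrees on replicate-constant data
  esr <- effect_summary(toy_trial(ch), "sprint5m", pairing = "replicate")
  expect_equal(esr$mean, -0.06)
})

test_that("baseline summaries report mean and SD of pre-test times", {
  df <- tibble::tibble(
    subject = c("A", "A", "B", "B"), replicate = c(1, 1, 1, 1),
    condition = c("control", "intervention", "control", "intervention"),
    outcome = "o", pre_time = c(1.0, 1.0, 0.9, 0.9),
    post_time = c(1.1, 1.0, 1.0, 0.9))
  bs <- baseline_summary(df, "o")
  expect_equal(bs$mean, 0.95)
  expect_equal(bs$sd, 0.05773503, tolerance = 1e-6)
  expect_equal(bs$n, 4)
  expect_error(baseline_summary(df, "x"), class = "cob_lookup_error")

  dfv <- dplyr::mutate(df, pre_time = 1.2)
  bsv <- baseline_summary(dfv, "o")
  expect_equal(bsv$mean, 1.2)
  expect_equal(bsv$sd, 0)
})

test_that("outcome correlations match a direct covariance-formula oracle", {
  # perfect linearity and antisymmetry
  base <- grid_changes(sprintf("P%d", 1:4))
  a <- dplyr::mutate(base, change = ifelse(condition == "intervention",
                                           seq(-0.1, 0.1, length.out = dplyr::n()),
                                           0))
  dat_a <- toy_trial(a, outcome = "oa")
  dat_b2 <- toy_trial(dplyr::mutate(a, change = 2 * change), outcome = "ob")
  dat_bn <- toy_trial(dplyr::mutate(a, change = -change), outcome = "ob")
  expect_equal(outcome_correlation(dplyr::bind_rows(dat_a, dat_b2),
                                   "oa", "ob")$r, 1)
  expect_equal(outcome_correlation(dplyr::bind_rows(dat_a, dat_bn),
                                   "oa", "ob")$r, -1)

  # fixed 14-pair fixture vs the covariance formula
  set.seed(99)
  subs <- sprintf("P%d", 1:7)
  mk <- function(oc) grid_changes(subs) |>
    dplyr::mutate(change = rnorm(dplyr::n(), 0, 0.05)) |>
    toy_trial(outcome = oc)
  dat <- dplyr::bind_rows(mk("oa"), mk("ob"))
  res <- outcome_correlation(dat, "oa", "ob")
  expect_equal(res$n, 14)
  da <- replicate_diffs_oracle(dat, "oa"); db <- replicate_diffs_oracle(dat, "ob")
  r_oracle <- sum((da - mean(da)) * (db - mean(db))) /
    sqrt(sum((da - mean(da))^2) * sum((db - mean(db))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  tstat <- r_oracle * sqrt((14 - 2) / (1 - r_oracle^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 12), tolerance = 1e-12)

  # per-subject unit
  expect_equal(outcome_correlation(dat, "oa", "ob", unit = "subject")$n, 7)

  two <- dplyr::filter(dat, subject %in% c("P1", "P2"))
  expect_error(outcome_correlation(two, "oa", "ob", unit = "subject"),
               class = "cob_insufficient_data_error")
})
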