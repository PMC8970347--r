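# Shared fixtures and independent oracles, all built in code.

# Minimal complete dataset: n subjects x 2 replicates x 2 conditions x one
# outcome, with change scores supplied directly (pre_time = 1).
toy_trial <- function(changes, outcome = "sprint5m") {
  # `changes`: tibble with subject, replicate, condition, change
  dplyr::mutate(changes, outcome = outcome, pre_time = 1,
                post_time = 1 + .data$change) |>
    dplyr::select("subject", "replicate", "condition", "outcome",
                  "pre_time", "post_time")
}

# Balanced change-score grid for the given per-cell values.
grid_changes <- function(subjects, n_replicates = 2) {
  tidyr::expand_grid(subject = subjects,
                     replicate = seq_len(n_replicates),
                     condition = c("control", "intervention"))
}

# Independent brute-force HPDI: explicit loop over every window of
# ceiling(level * n) sorted draws, earliest minimal window.
brute_hpdi <- function(draws, level) {
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(level * n)
  best_i <- 1
  best_w <- Inf
  for (i in seq_len(n - m + 1)) {
    w <- s[i + m - 1] - s[i]
    if (w < best_w) {   # strict: keeps the earliest among ties
      best_w <- w
      best_i <- i
    }
  }
  c(s[best_i], s[best_i + m - 1])
}

# Closed-form posterior of a two-group mean difference with known variance
# and flat priors on both group means.
conjugate_mean_diff <- function(d1, d0, sigma_sq) {
  list(mean = mean(d1) - mean(d0),
       sd = sqrt(sigma_sq * (1 / length(d1) + 1 / length(d0))))
}

quick_mcmc <- function(iterations = 1500, chains = 2, seed = 1) {
  mcmc_config(iterations = iterations, chains = chains, seed = seed)
}

prior_5m <- function() elicit_effect_prior(0.978, 0.05, 2)

# Per (subject, replicate) intervention-minus-control differences, ordered by
# subject then replicate, computed directly from the raw table.
replicate_diffs_oracle <- function(data, outcome) {
  d <- data[data$outcome == outcome, ]
  d <- d[order(d$subject, d$replicate, d$condition), ]
  ch <- d$post_time - d$pre_time
  int <- d$condition == "intervention"
  ch[int] - ch[!int]
}
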