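# Split R-hat and effective sample size, computed from the kept draws of
# each chain (each chain split in half so slow trends register as
# between-chain variance).

split_halves <- function(chains) {
  out <- list()
  for (x in chains) {
    n <- length(x)
    h <- n %/% 2
    out <- c(out, list(x[seq_len(h)], x[(n - h + 1):n]))
  }
  out
}

rhat_split <- function(chains) {
  cs <- split_halves(chains)
  n <- min(lengths(cs))
  cs <- lapply(cs, function(x) x[seq_len(n)])
  m <- length(cs)
  if (n < 2) return(NA_real_)
  wv <- vapply(cs, var, numeric(1))
  W <- mean(wv)
  if (!is.finite(W) || W == 0) return(NA_real_)   # constant draws: no ratio
  means <- vapply(cs, mean, numeric(1))
  B <- n * var(means)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

ess_draws <- function(chains, max_lag = NULL) {
  n <- min(lengths(chains))
  chains <- lapply(chains, function(x) x[seq_len(n)])
  m <- length(chains)
  if (n < 4) return(NA_real_)
  wv <- vapply(chains, var, numeric(1))
  W <- mean(wv)
  if (!is.finite(W) || W == 0) return(NA_real_)
  means <- vapply(chains, mean, numeric(1))
  var_plus <- (n - 1) / n * W + if (m > 1) n * var(means) / n else 0
  max_lag <- max_lag %||% min(n - 2, 1000)
  # mean autocovariance across chains
  acov <- sapply(chains, function(x) {
    stats::acf(x, lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  acov <- rowMeans(acov)
  rho <- 1 - (W - acov[-1] * n / (n - 1)) / var_plus
  # Geyer initial monotone positive sequence over lag pairs
  n_pairs <- length(rho) %/% 2
  tau <- 1
  prev <- Inf
  for (k in seq_len(n_pairs)) {
    p <- rho[2 * k - 1] + rho[2 * k]
    if (p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + 2 * p
  }
  max(m * n / tau, 1)
}

#' MCMC convergence diagnostics
#'
#' Split R-hat and effective sample size (ESS) per parameter, with a pass flag
#' against standard thresholds (R-hat < 1.05, ESS > 100).  With a single chain
#' R-hat cannot be computed and a warning is raised; parameters with constant
#' draws (e.g. pinned variance components) report `NA` rather than dividing
#' by a zero within-chain variance.
#'
#' @param fit A [fit_bayes()] result.
#' @param rhat_threshold,ess_threshold Pass thresholds.
#' @return Tibble with columns `parameter`, `mean`, `sd`, `rhat`, `ess`,
#'   `mcse`, `pass`.
#' @export
mcmc_diagnostics <- function(fit, rhat_threshold = 1.05, ess_threshold = 100) {
  stopifnot(inherits(fit, "bayes_fit"))
  pars <- setdiff(names(fit$draws), c("chain", "iteration"))
  single <- fit$config$chains < 2
  if (single) {
    warn("Single chain: R-hat unavailable, diagnostics limited to ESS.",
         class = "cob_diagnostics_warning")
  }
  rows <- lapply(pars, function(p) {
    per_chain <- split(fit$draws[[p]], fit$draws$chain)
    rh <- if (single) NA_real_ else rhat_split(per_chain)
    es <- ess_draws(per_chain)
    s <- sd(fit$draws[[p]])
    constant <- is.finite(s) && s == 0
    tibble::tibble(
      parameter = p,
      mean = mean(fit$draws[[p]]),
      sd = s,
      rhat = rh,
      ess = es,
      mcse = if (is.finite(es) && es > 0) s / sqrt(es) else NA_real_,
      pass = constant ||
        ((single || (!is.na(rh) && rh < rhat_threshold)) &&
           !is.na(es) && es > ess_threshold)
    )
  })
  dplyr::bind_rows(rows)
}

# Monte-Carlo standard error of the posterior mean of one parameter.
mcse_parameter <- function(fit, parameter) {
  per_chain <- split(fit$draws[[parameter]], fit$draws$chain)
  es <- ess_draws(per_chain)
  sd(fit$draws[[parameter]]) / sqrt(es)
}
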