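# Shared fixtures for the test suite.  Everything is generated in code.

# A degenerate spec with all fall-history mass on one level.
single_level_spec <- function(n = 1000L, rate = 0.43, theta = 1.06,
                              level = 1L, seed = 42L) {
  probs <- rep(0, 6)
  probs[level] <- 1
  cohort_spec(label = "single", n = n, category_probs = probs,
              baseline_rate = rate, rate_ratios = rep(1, 6), theta = theta,
              seed = seed)
}

# A small realistic spec (mixture over all six levels).
toy_spec <- function(n = 500L, seed = 7L, baseline = 0.6, theta = 1.1,
                     exposure = list(model = "fixed", value = 1),
                     label = "toy") {
  cohort_spec(label = label, n = n,
              category_probs = c(0.5, 0.2, 0.12, 0.08, 0.04, 0.06),
              baseline_rate = baseline,
              rate_ratios = c(1, 1.5, 1.2, 2.5, 3, 8),
              theta = theta, exposure = exposure, seed = seed)
}

# NB2 log-likelihood of a fitted fall_rate_model on its training table,
# written from the density directly so it is independent of the fitter.
nb2_loglik <- function(alpha, beta, theta, table, use_offset = FALSE) {
  lev <- categorize_prior_falls(table$prior_falls_12m)
  b <- stats::setNames(c(0, beta), c("0", "1", "2", "3", "4", "5+"))
  eta <- alpha + b[lev] +
    if (use_offset) log(table$exposure_years) else 0
  sum(stats::dnbinom(table$incident_falls, size = theta, mu = exp(eta),
                     log = TRUE))
}

# Brute-force REML maximizer over a tau2 grid (independent oracle for the
# Fisher-scoring estimator).
grid_reml_tau2 <- function(y, se, upper = 5, step = 1e-4) {
  grid <- seq(0, upper, by = step)
  v <- se^2
  ll <- vapply(grid, function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    -0.5 * (sum(log(v + t2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }, numeric(1))
  grid[which.max(ll)]
}

# First-stage fits of the three default synthetic cohorts at a given seed.
fit_default_cohorts <- function(seed = 1L, n = NULL) {
  specs <- default_cohort_specs(seed = seed)
  if (!is.null(n)) specs <- lapply(specs, function(s) { s$n <- n; s })
  tabs <- lapply(specs, generate_cohort)
  models <- Map(function(s, tab)
    fit_negative_binomial(tab, use_offset = s$exposure$model == "uniform",
                          label = s$label),
    specs, tabs)
  list(specs = specs, tables = tabs, models = models)
}
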