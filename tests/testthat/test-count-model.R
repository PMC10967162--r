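test_that("prior-fall counts map onto the six-level factor", {
  expect_equal(categorize_prior_falls(c(0, 1, 2, 3, 4)),
               c("0", "1", "2", "3", "4"))
  expect_equal(categorize_prior_falls(c(5, 7, 23)), rep("5+", 3))
  expect_equal(categorize_prior_falls(NA), NA_character_)
  expect_error(categorize_prior_falls(-1), "non-negative")
  expect_error(categorize_prior_falls(1.5), "integer")
})

test_that("complete-case filtering drops and reports incomplete rows", {
  tab <- generate_cohort(toy_spec(n = 50L))
  clean <- filter_complete_cases(tab)
  expect_equal(nrow(clean), 50L)
  expect_equal(attr(clean, "n_dropped"), 0L)

  tab$incident_falls[c(3, 9)] <- NA
  tab$prior_falls_12m[4] <- NA
  expect_message(out <- filter_complete_cases(tab), "dropped 3")
  expect_equal(nrow(out), 47L)
  expect_equal(attr(out, "n_dropped"), 3L)

  tab$incident_falls <- NA
  expect_error(filter_complete_cases(tab), "no complete cases")
})

test_that("the intercept-only Poisson limit recovers log of the mean", {
  # all participants at the reference level, theta fixed very large:
  # NB2 degenerates to Poisson whose ML intercept is log(sample mean)
  tab <- generate_cohort(single_level_spec(n = 800L, rate = 0.9, theta = 5,
                                           seed = 21L))
  fit <- suppressWarnings(
    fit_negative_binomial(tab, theta = 1e8, label = "poisson-limit"))
  expect_equal(fit$alpha, log(mean(tab$incident_falls)), tolerance = 1e-6)
  expect_true(all(is.na(fit$beta)))
  expect_equal(fit$dropped_levels, c("1", "2", "3", "4", "5+"))
})

test_that("theta -> infinity limit agrees with a Poisson regression oracle", {
  tab <- generate_cohort(toy_spec(n = 3000L, seed = 31L))
  fit <- fit_negative_binomial(tab, theta = 1e8, label = "nb-limit")
  lev <- factor(categorize_prior_falls(tab$prior_falls_12m),
                levels = prior_fall_levels())
  oracle <- glm(tab$incident_falls ~ lev, family = poisson())
  expect_equal(unname(c(fit$alpha, fit$beta)), unname(coef(oracle)),
               tolerance = 1e-4)
})

test_that("fitting recovers the generating parameters at large n", {
  spec <- default_cohort_specs(seed = 17L)$gerico
  spec$n <- 10000L
  tab <- generate_cohort(spec)
  fit <- fit_negative_binomial(tab, label = "recovery")
  truth <- c(log(spec$baseline_rate), log(spec$rate_ratios[-1]))
  est <- c(fit$alpha, fit$beta)
  se <- c(fit$se_alpha, fit$se_beta)
  expect_true(all(abs(est - truth) < 4 * se))
  expect_lt(abs(fit$theta - spec$theta), 4 * fit$se_theta)
  expect_true(fit$converged)
  # model invariants
  expect_true(all(se > 0))
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
})

test_that("the returned estimate is a local maximum of the NB2 likelihood", {
  tab <- generate_cohort(toy_spec(n = 1500L, seed = 13L))
  fit <- fit_negative_binomial(tab, label = "localmax")
  ll_hat <- nb2_loglik(fit$alpha, fit$beta, fit$theta, tab)
  for (j in 0:5) {
    for (d in c(-0.02, 0.02)) {
      alpha <- fit$alpha + if (j == 0) d else 0
      beta <- fit$beta
      if (j > 0) beta[j] <- beta[j] + d
      expect_lt(nb2_loglik(alpha, beta, fit$theta, tab), ll_hat)
    }
  }
  for (d in c(-0.1, 0.1))
    expect_lt(nb2_loglik(fit$alpha, fit$beta, fit$theta + d, tab), ll_hat)
})

test_that("the person-time offset rescales the intercept exactly", {
  spec <- toy_spec(n = 2000L, seed = 19L,
                   exposure = list(model = "uniform", min = 0.25, max = 1))
  tab <- generate_cohort(spec)
  fit <- fit_negative_binomial(tab, use_offset = TRUE, label = "offset")
  scaled <- tab
  scaled$exposure_years <- tab$exposure_years * 2.5
  fit2 <- fit_negative_binomial(scaled, use_offset = TRUE, label = "scaled")
  expect_equal(fit2$alpha, fit$alpha - log(2.5), tolerance = 1e-6)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-6)
})

test_that("degenerate inputs raise informative fitting errors", {
  tab <- generate_cohort(toy_spec(n = 200L))
  tab$incident_falls <- 0L
  expect_error(fit_negative_binomial(tab, label = "allzero"),
               "negative-binomial fit failed")

  tab2 <- generate_cohort(toy_spec(n = 50L))
  tab2$incident_falls[2] <- NA
  expect_error(fit_negative_binomial(tab2), "filter_complete_cases")
})

test_that("empty factor levels are dropped with a recorded warning", {
  spec <- toy_spec(n = 400L, seed = 23L)
  spec$category_probs <- c(0.5, 0.3, 0.2, 0, 0, 0)
  tab <- generate_cohort(spec)
  expect_warning(fit <- fit_negative_binomial(tab, label = "partial"),
                 "dropped from fit")
  expect_setequal(fit$dropped_levels, c("3", "4", "5+"))
  expect_true(all(is.na(fit$beta[c("b3", "b4", "b5+")])))
  expect_true(all(!is.na(fit$beta[c("b1", "b2")])))
  expect_error(predict_expected_falls(fit, "4", 1), "dropped during fitting")
})

test_that("rate-ratio tables apply the closed-form Wald interval", {
  m <- structure(list(label = "toy", reference_level = "0",
                      alpha = 0, se_alpha = 0.1,
                      beta = setNames(rep(0, 5),
                                      c("b1", "b2", "b3", "b4", "b5+")),
                      se_beta = setNames(rep(0.1, 5),
                                         c("b1", "b2", "b3", "b4", "b5+")),
                      theta = 1, se_theta = 0.1, n_fitted = 0L,
                      converged = TRUE, offset_used = FALSE,
                      dropped_levels = character()),
                 class = "fall_rate_model")
  tab <- rate_ratio_table(m)
  expect_equal(tab$estimate, rep(1, 6))
  expect_equal(tab$ci_low, rep(0.8220122347, 6), tolerance = 1e-8)
  expect_equal(tab$ci_high, rep(1.216526905, 6), tolerance = 1e-8)

  m$se_beta[] <- 0
  degenerate <- rate_ratio_table(m)
  expect_equal(degenerate$ci_low[-1], degenerate$estimate[-1])
  expect_equal(degenerate$ci_high[-1], degenerate$estimate[-1])
})

test_that("expected falls multiply baseline, rate ratio and exposure", {
  fit <- fit_default_cohorts(seed = 29L)$models$gerico
  p1 <- predict_expected_falls(fit, "0", 1)
  expect_equal(p1, exp(fit$alpha))
  expect_equal(predict_expected_falls(fit, "5+", 1),
               exp(fit$alpha + fit$beta[["b5+"]]))
  # linear in exposure, strictly increasing
  expect_equal(predict_expected_falls(fit, "0", 0.5), p1 / 2)
  exposures <- c(0.25, 0.5, 1, 2)
  expect_true(all(diff(predict_expected_falls(
    fit, rep("2", 4), exposures)) > 0))
  expect_error(predict_expected_falls(fit, "6", 1), "unknown")
  expect_error(predict_expected_falls(fit, "0", 0), "positive")
})

test_that("models round-trip through JSON", {
  fit <- fit_default_cohorts(seed = 37L)$models$sct
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, f)
  back <- read_model_json(f)
  for (field in c("alpha", "se_alpha", "beta", "se_beta", "theta",
                  "se_theta", "n_fitted", "offset_used", "label"))
    expect_equal(back[[field]], fit[[field]], tolerance = 1e-12,
                 label = field)
  expect_equal(back$vcov, fit$vcov, tolerance = 1e-12)
  p <- predict_expected_falls(back, c("0", "3"), c(1, 2))
  expect_equal(p, predict_expected_falls(fit, c("0", "3"), c(1, 2)))
})
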