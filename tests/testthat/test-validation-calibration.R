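make_model <- function(alpha, beta = rep(0, 5), theta = 1,
                       label = "manual") {
  bn <- c("b1", "b2", "b3", "b4", "b5+")
  structure(list(label = label, reference_level = "0",
                 alpha = alpha, se_alpha = 0.1,
                 beta = setNames(beta, bn),
                 se_beta = setNames(rep(0.1, 5), bn),
                 vcov = diag(0.01, 6), theta = theta, se_theta = 0.1,
                 n_fitted = 0L, converged = TRUE, offset_used = FALSE,
                 dropped_levels = character()),
            class = "fall_rate_model")
}

test_that("mean absolute prediction error matches hand computation", {
  # outcomes (0, 1, 3) vs predictions (0.5, 0.5, 2.0) -> 2/3
  m <- make_model(alpha = log(0.5), beta = c(0, log(4), 0, 0, 0))
  tab <- data.frame(id = letters[1:3],
                    prior_falls_12m = c(0L, 0L, 2L),
                    incident_falls = c(0L, 1L, 3L),
                    exposure_years = 1)
  expect_equal(mean_absolute_prediction_error(m, tab), 2 / 3)

  # predictions equal to outcomes -> 0
  exact <- make_model(alpha = log(2))
  tab0 <- data.frame(id = "a", prior_falls_12m = 0L, incident_falls = 2L,
                     exposure_years = 1)
  expect_equal(mean_absolute_prediction_error(exact, tab0), 0)
})

test_that("MAE is invariant to row order and dataset duplication", {
  fits <- fit_default_cohorts(seed = 67L)
  m <- fits$models$gerico
  tab <- fits$tables$gerico
  mae <- mean_absolute_prediction_error(m, tab)
  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  expect_equal(mean_absolute_prediction_error(m, shuffled), mae)
  doubled <- rbind(tab, tab)
  expect_equal(mean_absolute_prediction_error(m, doubled), mae)
  expect_error(mean_absolute_prediction_error(
    m, transform(tab, incident_falls = NA)), "filter_complete_cases")
})

test_that("cross-validation matrix has apparent errors on the diagonal", {
  fits <- fit_default_cohorts(seed = 71L)
  mat <- cross_validation_matrix(fits$models, fits$tables)
  expect_equal(dim(mat), c(3L, 3L))
  for (nm in names(fits$models))
    expect_equal(mat[nm, nm],
                 mean_absolute_prediction_error(fits$models[[nm]],
                                                fits$tables[[nm]]))

  # identical models give identical rows
  twice <- cross_validation_matrix(list(a = fits$models$sct,
                                        b = fits$models$sct),
                                   fits$tables)
  expect_equal(unname(twice["a", ]), unname(twice["b", ]))

  one <- cross_validation_matrix(fits$models["gerico"],
                                 fits$tables["gerico"])
  expect_equal(dim(one), c(1L, 1L))
  expect_equal(one[1, 1], mat["gerico", "gerico"])
})

test_that("self-recalibration returns a near-zero constant", {
  fits <- fit_default_cohorts(seed = 73L)
  for (nm in names(fits$models)) {
    cal <- calibration_in_the_large(fits$models[[nm]], fits$tables[[nm]])
    expect_lt(abs(cal$alpha_new), 0.02)
    # updated predictor differs from p0 by exactly alpha_new, everywhere
    expect_equal(unique(round(cal$p1 - cal$p0, 12)),
                 round(cal$alpha_new, 12))
    # mean updated prediction approximately matches the observed mean
    # (the NB intercept fit matches a dispersion-weighted mean, so the
    # agreement is approximate; see the methods vignette)
    expect_equal(mean(exp(cal$p1)),
                 mean(fits$tables[[nm]]$incident_falls),
                 tolerance = 0.1)
  }
})

test_that("a doubled-rate cohort recalibrates to about log 2", {
  spec <- toy_spec(n = 10000L, seed = 79L)
  base <- generate_cohort(spec)
  model <- fit_negative_binomial(base, label = "base")

  doubled_spec <- spec
  doubled_spec$baseline_rate <- spec$baseline_rate * 2
  doubled_spec$seed <- 80L
  doubled <- generate_cohort(doubled_spec)
  cal <- calibration_in_the_large(model, doubled)
  expect_lt(abs(cal$alpha_new - log(2)), 3 * cal$se_alpha_new)
  expect_gt(cal$alpha_new, 0.5)
})

test_that("recalibration is idempotent", {
  fits <- fit_default_cohorts(seed = 83L)
  model <- fits$models$gerico
  target <- fits$tables$sct
  cal <- calibration_in_the_large(model, target)
  updated <- recalibrate_model(model, cal)
  again <- calibration_in_the_large(updated, target)
  expect_lt(abs(again$alpha_new), 1e-6)
})

test_that("recalibration can carry the existing dispersion", {
  fits <- fit_default_cohorts(seed = 89L)
  cal <- calibration_in_the_large(fits$models$gerico, fits$tables$kfps,
                                  theta = "carry")
  expect_equal(cal$theta_new, fits$models$gerico$theta)
  fresh <- calibration_in_the_large(fits$models$gerico, fits$tables$kfps)
  expect_false(identical(fresh$theta_new, cal$theta_new))
})

test_that("recalibration constants track baseline-rate differences", {
  # two cohorts identical except for the baseline rate
  lo_spec <- toy_spec(n = 8000L, seed = 91L, baseline = 0.43)
  hi_spec <- toy_spec(n = 8000L, seed = 92L, baseline = 0.83)
  lo <- generate_cohort(lo_spec)
  hi <- generate_cohort(hi_spec)
  m_lo <- fit_negative_binomial(lo, label = "lo")
  cal <- calibration_in_the_large(m_lo, hi)
  expect_lt(abs(cal$alpha_new - log(0.83 / 0.43)),
            3 * cal$se_alpha_new + 0.02)
  expect_gt(cal$alpha_new, 0.3)
})

test_that("rootogram frequencies are conserved and follow the NB2 pmf", {
  # two participants with mu = theta = 1: NB2 pmf at 0 is 1/2 each
  m <- make_model(alpha = 0, theta = 1)
  toy <- data.frame(id = c("a", "b"), prior_falls_12m = 0L,
                    incident_falls = c(0L, 2L), exposure_years = 1)
  rg <- rootogram(m, toy, K = 5L)
  expect_equal(rg$expected[1], 1.0, tolerance = 1e-9)
  expect_equal(sum(rg$observed), 2)
  expect_equal(sum(rg$expected), 2, tolerance = 1e-6)
  expect_equal(rg$count[7], ">=6")

  # hanging geometry: bars hang from the expected curve down by sqrt(obs)
  expect_equal(rg$bar_ymax, rg$sqrt_expected)
  expect_equal(rg$bar_ymax - rg$bar_ymin, rg$sqrt_observed)

  fits <- fit_default_cohorts(seed = 97L)
  fm <- meta_analyze_models(fits$models)
  for (nm in names(fits$tables)) {
    r <- rootogram(fm$overall, fits$tables[[nm]])
    n <- nrow(fits$tables[[nm]])
    expect_equal(sum(r$observed), n)
    expect_equal(sum(r$expected), n, tolerance = 1e-6)
    expect_true(all(r$expected >= 0))
  }
  p <- plot(rootogram(fm$overall, fits$tables$gerico))
  expect_s3_class(p, "ggplot")
})
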