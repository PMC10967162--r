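#' Mean absolute prediction error of a model on a cohort
#'
#' Mean over participants of `|incident_falls - expected falls|`, with the
#' expected count from [predict_expected_falls()] at each participant's
#' fall-history level and exposure.  On the model's own training cohort this
#' is the apparent error; on an unseen cohort, the external error.
#' Predictions use the model coefficients as-is (no recalibration); a
#' recalibrated error is available by passing the updated model from
#' [calibration_in_the_large()].
#'
#' @param model A `fall_rate_model`.
#' @param table Cohort table with complete model variables.
#' @return Non-negative scalar (falls).
#' @export
mean_absolute_prediction_error <- function(model, table) {
  vars <- c("prior_falls_12m", "incident_falls", "exposure_years")
  if (anyNA(table[vars]))
    stop("table contains missing model variables; apply ",
         "filter_complete_cases() first", call. = FALSE)
  pred <- predict_expected_falls(
    model, categorize_prior_falls(table$prior_falls_12m),
    table$exposure_years)
  mean(abs(table$incident_falls - pred))
}

#' External-validation error matrix
#'
#' Applies every model to every cohort: entry `(m, d)` is the mean absolute
#' prediction error of model `m` on dataset `d`.  When a model's own
#' training cohort is among the datasets, the corresponding entry is its
#' apparent error.
#'
#' @param models List of `fall_rate_model` objects (names or labels become
#'   row names).
#' @param tables List of cohort tables (names become column names).
#' @return Numeric matrix, models in rows, datasets in columns.
#' @export
cross_validation_matrix <- function(models, tables) {
  if (length(models) < 1L || length(tables) < 1L)
    stop("need at least one model and one table", call. = FALSE)
  out <- vapply(tables, function(tab)
    vapply(models, mean_absolute_prediction_error, numeric(1), table = tab),
    numeric(length(models)))
  out <- matrix(out, nrow = length(models),
                dimnames = list(
                  names(models) %||%
                    vapply(models, function(m) m$label, character(1)),
                  names(tables) %||% paste0("data", seq_along(tables))))
  out
}

#' Calibration-in-the-large for a count model
#'
#' Recalibrates an existing fall-rate model to a new cohort on the link
#' scale in three steps: (1) compute each new participant's linear
#' predictor `p0` under the existing model (including the log person-time
#' offset); (2) fit a fresh intercept-only NB2 regression of the new
#' outcomes with `p0` as an offset; (3) take that fit's intercept
#' `alpha_new` as the recalibration constant, giving updated predictors
#' `p1 = alpha_new + p0`.  A model applied to a population with the same
#' baseline rate yields `alpha_new` near 0; a population whose rates are
#' uniformly `c`-fold higher yields `alpha_new` near `log(c)`.
#'
#' The dispersion of the recalibration fit is re-estimated by default
#' (fresh NB fit); `theta = "carry"` keeps the existing model's `theta`
#' fixed instead.
#'
#' @param model A `fall_rate_model`.
#' @param table New cohort table with complete model variables.
#' @param theta `"reestimate"` (default) or `"carry"`.
#' @return A `calibration_result`: `alpha_new`, `se_alpha_new`,
#'   `theta_new`, and the per-participant link-scale predictors `p0` and
#'   `p1` (`p1 - p0` is constant and equals `alpha_new`).
#' @export
#' @examples
#' spec <- default_cohort_specs(seed = 5)$kfps
#' tab <- generate_cohort(spec)
#' m <- fit_negative_binomial(tab, label = "kfps")
#' calibration_in_the_large(m, tab)$alpha_new  # ~ 0 on its own data
calibration_in_the_large <- function(model, table,
                                     theta = c("reestimate", "carry")) {
  theta <- match.arg(theta)
  vars <- c("prior_falls_12m", "incident_falls", "exposure_years")
  if (anyNA(table[vars]))
    stop("table contains missing model variables; apply ",
         "filter_complete_cases() first", call. = FALSE)
  p0 <- linear_predictor(model, table)
  dat <- data.frame(y = table$incident_falls, p0 = p0)
  ctrl <- glm.control(epsilon = 1e-10, maxit = 200L)
  fit <- tryCatch(
    if (theta == "carry") {
      glm(y ~ 1 + offset(p0), data = dat,
          family = MASS::negative.binomial(model$theta), control = ctrl)
    } else {
      MASS::glm.nb(y ~ 1 + offset(p0), data = dat, control = ctrl)
    },
    error = function(e)
      stop("recalibration fit failed: ", conditionMessage(e), call. = FALSE))
  alpha_new <- unname(coef(fit)[["(Intercept)"]])
  structure(
    list(alpha_new = alpha_new,
         se_alpha_new = sqrt(vcov(fit)[1, 1]),
         theta_new = if (theta == "carry") model$theta else fit$theta,
         theta_mode = theta,
         p0 = p0, p1 = alpha_new + p0,
         model = model$label),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibration-in-the-large of model '%s': alpha_new = %.4f (SE %.4f)\n",
    x$model, x$alpha_new, x$se_alpha_new))
  cat(sprintf("  theta of recalibration fit: %.3f (%s), n = %d\n",
              x$theta_new, x$theta_mode, length(x$p0)))
  invisible(x)
}

#' Apply a recalibration constant to a model
#'
#' Returns a copy of the model with `alpha_new` added to its intercept, so
#' that its linear predictors equal the updated `p1` of
#' [calibration_in_the_large()].
#'
#' @param model A `fall_rate_model`.
#' @param calibration A `calibration_result`.
#' @return The shifted `fall_rate_model`.
#' @export
recalibrate_model <- function(model, calibration) {
  model$alpha <- model$alpha + calibration$alpha_new
  model$label <- paste0(model$label, "+recal")
  model
}

#' Hanging rootogram of observed versus expected fall counts
#'
#' Marginal calibration diagnostic for the count model: for each fall count
#' `k = 0, ..., K` the expected frequency is the sum over participants of
#' the NB2 probability `Pr(Y = k | mu_i, theta)` with the participant's own
#' mean `mu_i`; counts above `K` are pooled into a single tail bin on both
#' the observed and expected side, so each side sums exactly to `n`.  Bars
#' are drawn on the square-root scale hanging from the expected curve: the
#' bar for count `k` spans `sqrt(E_k) - sqrt(O_k)` to `sqrt(E_k)`, so bars
#' overshooting below the x-axis flag underestimation and floating bars that
#' do not reach it flag overestimation.
#'
#' @param model A `fall_rate_model`.
#' @param table Cohort table with complete model variables.
#' @param K Largest individually-binned count; the tail bin is `>= K + 1`.
#' @return A `rootogram` data frame with columns `count` (label, last is
#'   the tail bin), `observed`, `expected`, `sqrt_observed`,
#'   `sqrt_expected`, `bar_ymin`, `bar_ymax`; attributes `n`, `K`,
#'   `model`.
#' @export
rootogram <- function(model, table, K = 20L) {
  vars <- c("prior_falls_12m", "incident_falls", "exposure_years")
  if (anyNA(table[vars]))
    stop("table contains missing model variables; apply ",
         "filter_complete_cases() first", call. = FALSE)
  stopifnot(K >= 1)
  mu <- exp(linear_predictor(model, table))
  n <- nrow(table)
  y <- table$incident_falls

  observed <- c(vapply(0:K, function(k) sum(y == k), numeric(1)),
                sum(y > K))
  expected_body <- vapply(0:K, function(k)
    sum(dnbinom(k, size = model$theta, mu = mu)), numeric(1))
  expected <- c(expected_body, n - sum(expected_body))

  sqrt_obs <- sqrt(observed)
  sqrt_exp <- sqrt(pmax(expected, 0))
  out <- data.frame(
    count = c(as.character(0:K), paste0(">=", K + 1)),
    observed = observed,
    expected = expected,
    sqrt_observed = sqrt_obs,
    sqrt_expected = sqrt_exp,
    bar_ymin = sqrt_exp - sqrt_obs,
    bar_ymax = sqrt_exp)
  attr(out, "n") <- n
  attr(out, "K") <- K
  attr(out, "model") <- model$label
  class(out) <- c("rootogram", "data.frame")
  out
}

#' Plot a hanging rootogram
#'
#' Grey bars (observed, hanging from the expected curve) with the expected
#' frequency curve in red, both on the square-root scale.
#'
#' @param x A `rootogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.rootogram <- function(x, ...) {
  d <- as.data.frame(x)
  d$pos <- seq_len(nrow(d)) - 1
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$pos - 0.4,
                                    xmax = .data$pos + 0.4,
                                    ymin = .data$bar_ymin,
                                    ymax = .data$bar_ymax),
                       fill = "grey70", colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$sqrt_expected),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$sqrt_expected),
                        colour = "firebrick", size = 1.2) +
    ggplot2::scale_x_continuous(breaks = d$pos, labels = d$count) +
    ggplot2::labs(x = "number of falls",
                  y = expression(sqrt("frequency")),
                  title = paste0("Hanging rootogram: model '",
                                 attr(x, "model"), "'")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 45, hjust = 1))
}
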