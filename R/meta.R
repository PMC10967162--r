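#' Recover a log-scale estimate from a published point and interval
#'
#' Converts a published rate (or rate ratio) with its 95% confidence
#' interval into the log-scale estimate and standard error that the
#' second-stage meta-analysis needs: `y = log(point)`,
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.96)`.  This is how
#' per-cohort coefficients printed only on the response scale re-enter the
#' pooling machinery.
#'
#' @param point,ci_low,ci_high Published estimate and 95% limits on the
#'   response (rate/ratio) scale; all positive, with
#'   `ci_low <= point <= ci_high`.
#' @param study Optional label(s) carried along.
#' @return `data.frame` with columns `study`, `y`, `se` (one row per
#'   estimate).
#' @export
#' @examples
#' log_scale_from_ci(2.55, 1.52, 4.29)
log_scale_from_ci <- function(point, ci_low, ci_high,
                              study = as.character(seq_along(point))) {
  if (any(ci_low <= 0) || any(point < ci_low) || any(ci_high < point))
    stop("need 0 < ci_low <= point <= ci_high for every estimate",
         call. = FALSE)
  se <- (log(ci_high) - log(ci_low)) / (2 * 1.96)
  if (any(se <= 0))
    stop("degenerate interval (ci_low == ci_high) gives se = 0; ",
         "a positive standard error is required", call. = FALSE)
  data.frame(study = study, y = log(point), se = se, row.names = NULL)
}

# REML restricted log-likelihood of the random-effects model
# y_i ~ N(mu, se_i^2 + tau2), intercept-only design (constants dropped).
reml_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

#' REML estimate of the between-study variance
#'
#' Maximizes the restricted likelihood of the random-effects model
#' `y_i ~ Normal(mu, se_i^2 + tau^2)` over `tau^2 >= 0` by Fisher scoring
#' (DerSimonian-Laird start, step-halving safeguard, boundary at zero),
#' iterated to a relative change below `tol`.
#'
#' @param y Study estimates on the analysis scale (log scale for rates and
#'   rate ratios, linear for the dispersion parameter).
#' @param se Within-study standard errors (> 0), same length as `y`.
#' @param tol Convergence tolerance on the change in `tau^2`.
#' @param maxit Maximum Fisher-scoring iterations.
#' @return Non-negative `tau^2`.
#' @export
#' @examples
#' est <- log_scale_from_ci(c(0.43, 0.83, 0.61), c(0.35, 0.61, 0.54),
#'                          c(0.52, 1.14, 0.70))
#' reml_tau2(est$y, est$se)
reml_tau2 <- function(y, se, tol = 1e-10, maxit = 100L) {
  k <- length(y)
  if (k < 2L)
    stop("meta-analysis requires >= 2 studies", call. = FALSE)
  stopifnot(length(se) == k, all(se > 0), all(is.finite(y)))
  v <- se^2

  # DerSimonian-Laird starting value
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))

  for (iter in seq_len(maxit)) {
    w <- 1 / (v + tau2)
    sw <- sum(w)
    mu <- sum(w * y) / sw
    # score and expected information of the restricted likelihood in tau2
    tr_p <- sw - sum(w^2) / sw
    score <- -0.5 * tr_p + 0.5 * sum(w^2 * (y - mu)^2)
    info <- 0.5 * (sum(w^2) - 2 * sum(w^3) / sw + (sum(w^2))^2 / sw^2)
    if (info <= 0) break
    step <- score / info
    new <- max(0, tau2 + step)
    # step-halving: never accept a drop in the restricted likelihood
    ll_old <- reml_loglik(tau2, y, v)
    for (h in 1:30) {
      if (reml_loglik(new, y, v) >= ll_old - 1e-13) break
      step <- step / 2
      new <- max(0, tau2 + step)
    }
    if (abs(new - tau2) < tol * (1 + tau2)) {
      tau2 <- new
      break
    }
    tau2 <- new
  }
  # boundary: if the score is negative at zero the maximum is tau2 = 0
  if (tau2 < tol) {
    w <- 1 / v
    mu <- sum(w * y) / sum(w)
    if (-0.5 * (sum(w) - sum(w^2) / sum(w)) +
        0.5 * sum(w^2 * (y - mu)^2) <= 0)
      tau2 <- 0
  }
  tau2
}

#' Higgins I-squared heterogeneity percentage
#'
#' The tau-squared-based (Higgins-Thompson) form:
#' `I2 = 100 * tau2 / (tau2 + s2)` with the typical within-study variance
#' `s2 = (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))`, fixed-effect weights
#' `w = 1/se^2`.  Used with a REML `tau2`; for the classical Q-based form
#' see [i2_from_q()].
#'
#' @param se Within-study standard errors (> 0).
#' @param tau2 Between-study variance (>= 0), e.g. from [reml_tau2()].
#' @return Percentage in `[0, 100]`.
#' @export
higgins_i2 <- function(se, tau2) {
  k <- length(se)
  if (k < 2L)
    stop("I-squared requires >= 2 studies", call. = FALSE)
  stopifnot(all(se > 0), tau2 >= 0)
  w <- 1 / se^2
  s2 <- (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  min(100, max(0, 100 * tau2 / (tau2 + s2)))
}

#' @describeIn higgins_i2 Q-based form `100 * max(0, Q - df) / Q`, exposed
#'   for comparison with the tau-squared-based default.
#' @param Q Cochran Q statistic.
#' @param df Its degrees of freedom (`k - 1`).
#' @export
i2_from_q <- function(Q, df) {
  if (Q <= 0) return(0)
  min(100, max(0, 100 * (Q - df) / Q))
}

#' Inverse-variance random-effects pooling
#'
#' Pools study estimates with weights `w_i = 1 / (se_i^2 + tau2)`:
#' `mu = sum(w y) / sum(w)`, `se_mu = sum(w)^(-1/2)`, 95% limits
#' `mu +/- 1.96 se_mu` (plain normal interval, no Knapp-Hartung
#' adjustment).  Cochran's Q is computed with fixed-effect weights
#' `1/se^2`, and Higgins I-squared is attached when `k >= 2`.
#'
#' @inheritParams reml_tau2
#' @param tau2 Between-study variance, usually from [reml_tau2()].
#' @param study Optional study labels stored with the result.
#' @return A `meta_result`: `mu`, `se_mu`, `ci95`, `tau2`, `i2`, `Q`, `k`,
#'   plus the inputs.
#' @export
#' @examples
#' est <- log_scale_from_ci(c(10.02, 7.39, 7.40), c(6.17, 3.77, 4.15),
#'                          c(16.27, 14.46, 13.20))
#' res <- pool_random_effects(est$y, est$se, reml_tau2(est$y, est$se))
#' exp(res$mu)
pool_random_effects <- function(y, se, tau2, study = NULL) {
  k <- length(y)
  if (k < 1L)
    stop("pooling requires >= 1 study", call. = FALSE)
  stopifnot(length(se) == k, all(se > 0), tau2 >= 0)
  w <- 1 / (se^2 + tau2)
  mu <- sum(w * y) / sum(w)
  se_mu <- 1 / sqrt(sum(w))
  wf <- 1 / se^2
  muf <- sum(wf * y) / sum(wf)
  q <- sum(wf * (y - muf)^2)
  structure(
    list(mu = mu, se_mu = se_mu,
         ci95 = c(low = mu - 1.96 * se_mu, high = mu + 1.96 * se_mu),
         tau2 = tau2,
         i2 = if (k >= 2L) higgins_i2(se, tau2) else NA_real_,
         Q = q, k = k,
         y = y, se = se, study = study),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Random-effects pooled estimate (k = %d): %.4f (95%% CI %.4f to %.4f)\n",
    x$k, x$mu, x$ci95[["low"]], x$ci95[["high"]]))
  cat(sprintf("  tau2 = %.4g, I2 = %s, Q = %.3f\n", x$tau2,
              if (is.na(x$i2)) "NA" else sprintf("%.2f%%", x$i2), x$Q))
  invisible(x)
}

#' One-call REML random-effects meta-analysis
#'
#' Convenience wrapper: [reml_tau2()] followed by [pool_random_effects()].
#'
#' @inheritParams pool_random_effects
#' @return A `meta_result`.
#' @export
meta_analyze <- function(y, se, study = NULL) {
  pool_random_effects(y, se, reml_tau2(y, se), study = study)
}

#' Pool first-stage models into an overall fall-rate model
#'
#' The second stage of the two-stage meta-analysis: each coefficient of the
#' first-stage models — the log baseline rate `alpha`, the five log rate
#' ratios, and the dispersion `theta` — is pooled separately across cohorts
#' by REML random-effects meta-analysis with inverse-variance weights.
#' Rate coefficients are pooled on the log scale; `theta` on the linear
#' scale by default (its published intervals are symmetric on that scale),
#' with log-scale pooling available via `theta_scale = "log"` (delta-method
#' SEs).
#'
#' A coefficient available (non-missing) in fewer than two models is not
#' pooled; it is reported in `$skipped` and left `NA` in the overall model.
#'
#' @param models List of >= 2 `fall_rate_model` objects sharing the
#'   six-level factor coding.
#' @param theta_scale `"linear"` (default) or `"log"`.
#' @return A `fall_meta` object: `$overall` (a `fall_rate_model` assembled
#'   from the pooled coefficients, diagonal covariance), `$per_coefficient`
#'   (named list of `meta_result`), `$skipped` (coefficient names not
#'   pooled).
#' @export
#' @examples
#' specs <- default_cohort_specs(seed = 11)
#' models <- lapply(specs, function(s)
#'   fit_negative_binomial(generate_cohort(s), label = s$label,
#'                         use_offset = s$exposure$model == "uniform"))
#' fm <- meta_analyze_models(models)
#' exp(fm$overall$alpha)
meta_analyze_models <- function(models, theta_scale = c("linear", "log")) {
  theta_scale <- match.arg(theta_scale)
  if (length(models) < 2L)
    stop("meta-analysis requires >= 2 studies", call. = FALSE)
  labels <- vapply(models, function(m) m$label, character(1))

  coef_names <- c("alpha", paste0("b", prior_fall_levels()[-1]), "theta")
  get_est <- function(m, cn) {
    if (cn == "alpha") c(m$alpha, m$se_alpha)
    else if (cn == "theta") {
      if (theta_scale == "log") c(log(m$theta), m$se_theta / m$theta)
      else c(m$theta, m$se_theta)
    } else c(m$beta[[cn]], m$se_beta[[cn]])
  }

  per_coef <- list()
  skipped <- character()
  for (cn in coef_names) {
    ests <- vapply(models, get_est, numeric(2), cn = cn)
    ok <- !is.na(ests[1, ]) & !is.na(ests[2, ]) & ests[2, ] > 0
    if (sum(ok) < 2L) {
      skipped <- c(skipped, cn)
      next
    }
    per_coef[[cn]] <- meta_analyze(ests[1, ok], ests[2, ok],
                                   study = labels[ok])
  }

  pooled <- function(cn, what = "mu") {
    if (is.null(per_coef[[cn]])) NA_real_ else per_coef[[cn]][[what]]
  }
  beta_names <- paste0("b", prior_fall_levels()[-1])
  beta <- setNames(vapply(beta_names, pooled, numeric(1)), beta_names)
  se_beta <- setNames(vapply(beta_names, pooled, numeric(1), what = "se_mu"),
                      beta_names)
  theta_mu <- pooled("theta")
  theta_se <- pooled("theta", "se_mu")
  if (theta_scale == "log" && !is.na(theta_mu)) {
    theta_se <- theta_se * exp(theta_mu)
    theta_mu <- exp(theta_mu)
  }
  par_names <- c("alpha", beta_names)
  se_all <- c(pooled("alpha", "se_mu"), se_beta)
  vc <- diag(se_all^2)
  dimnames(vc) <- list(par_names, par_names)

  overall <- structure(
    list(label = "overall", reference_level = "0",
         alpha = pooled("alpha"), se_alpha = pooled("alpha", "se_mu"),
         beta = beta, se_beta = se_beta, vcov = vc,
         theta = theta_mu, se_theta = theta_se,
         n_fitted = sum(vapply(models, function(m) m$n_fitted, numeric(1))),
         converged = all(vapply(models, function(m) isTRUE(m$converged),
                                logical(1))),
         offset_used = FALSE,
         dropped_levels = sub("^b", "",
                              grep("^b", skipped, value = TRUE))),
    class = "fall_rate_model")

  structure(list(overall = overall, per_coefficient = per_coef,
                 skipped = skipped, studies = labels),
            class = "fall_meta")
}

#' @export
print.fall_meta <- function(x, ...) {
  cat("Two-stage meta-analysis of", length(x$studies), "fall-rate models (",
      paste(x$studies, collapse = ", "), ")\n")
  print(meta_result_table(x), digits = 3)
  if (length(x$skipped))
    cat("  not pooled (present in < 2 models):",
        paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate pooled coefficients with heterogeneity measures
#'
#' One row per pooled coefficient: the overall estimate with its 95%
#' interval on the response scale (rates and rate ratios exponentiated,
#' `theta` as pooled), `tau2` and Higgins `I2`.  Mirrors the layout of a
#' published coefficient table and is what
#' [run_full_pipeline()] writes as the meta CSV.
#'
#' @param fm A `fall_meta` from [meta_analyze_models()].
#' @return `data.frame` with columns `coefficient`, `estimate`, `ci_low`,
#'   `ci_high`, `tau2`, `i2`, `k`.
#' @export
meta_result_table <- function(fm) {
  rows <- lapply(names(fm$per_coefficient), function(cn) {
    r <- fm$per_coefficient[[cn]]
    on_log <- cn != "theta"
    tr <- if (on_log) exp else identity
    data.frame(coefficient = cn,
               estimate = tr(r$mu),
               ci_low = tr(r$ci95[["low"]]),
               ci_high = tr(r$ci95[["high"]]),
               tau2 = r$tau2, i2 = r$i2, k = r$k)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Forest-plot data and figure for the pooled coefficients
#'
#' `forest_data()` stacks every study estimate and the pooled estimate per
#' coefficient on the response scale; `plot_forest()` renders the usual
#' forest plot (one panel per coefficient, pooled estimate highlighted).
#'
#' @param fm A `fall_meta`.
#' @return `forest_data()`: a `data.frame` with columns `coefficient`,
#'   `study`, `estimate`, `ci_low`, `ci_high`, `pooled`;
#'   `plot_forest()`: a ggplot object.
#' @export
forest_data <- function(fm) {
  rows <- lapply(names(fm$per_coefficient), function(cn) {
    r <- fm$per_coefficient[[cn]]
    tr <- if (cn == "theta") identity else exp
    studies <- data.frame(
      coefficient = cn, study = r$study %||% as.character(seq_len(r$k)),
      estimate = tr(r$y), ci_low = tr(r$y - 1.96 * r$se),
      ci_high = tr(r$y + 1.96 * r$se), pooled = FALSE)
    overall <- data.frame(
      coefficient = cn, study = "overall", estimate = tr(r$mu),
      ci_low = tr(r$ci95[["low"]]), ci_high = tr(r$ci95[["high"]]),
      pooled = TRUE)
    rbind(studies, overall)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname forest_data
#' @export
plot_forest <- function(fm) {
  d <- forest_data(fm)
  d$study <- factor(d$study, levels = rev(unique(d$study)))
  d$coefficient <- factor(d$coefficient, levels = unique(d$coefficient))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$study,
                                  colour = .data$pooled)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled), size = 2) +
    ggplot2::facet_wrap(~coefficient, scales = "free_x") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::labs(x = "rate / rate ratio (log axis)", y = NULL,
                  title = "Per-study and pooled fall-rate coefficients") +
    ggplot2::theme_minimal()
}
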