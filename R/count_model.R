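#' Code a prior-fall count as the six-level fall-history factor
#'
#' Counts 0--4 map to their own level; any count of five or more maps to the
#' open-ended level `"5+"`.  Level `"0"` is the reference category of all
#' models in the package.
#'
#' @param count Vector of non-negative integer prior-fall counts.
#' @return Character vector of levels in `{"0","1","2","3","4","5+"}`;
#'   `NA` propagates.
#' @export
#' @examples
#' categorize_prior_falls(c(0, 3, 7))
categorize_prior_falls <- function(count) {
  ok <- is.na(count) | (is.numeric(count) & count >= 0 & count == round(count))
  if (!all(ok))
    stop("prior-fall counts must be non-negative integers", call. = FALSE)
  out <- ifelse(count >= 5, "5+", as.character(as.integer(count)))
  out[is.na(count)] <- NA_character_
  out
}

#' Drop participants with missing model variables
#'
#' Complete-case filter over the three model variables (`prior_falls_12m`,
#' `incident_falls`, `exposure_years`).
#'
#' @param table A cohort table.
#' @return The filtered table, with the number of dropped rows attached as
#'   attribute `n_dropped` (also reported via `message()`).
#' @export
filter_complete_cases <- function(table) {
  keep <- stats::complete.cases(
    table[c("prior_falls_12m", "incident_falls", "exposure_years")])
  out <- table[keep, , drop = FALSE]
  n_dropped <- sum(!keep)
  if (nrow(out) == 0L)
    stop("no complete cases remain after filtering", call. = FALSE)
  if (n_dropped > 0L)
    message("filter_complete_cases: dropped ", n_dropped, " of ",
            nrow(table), " rows")
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Fit the first-stage negative-binomial fall-rate model
#'
#' Fits `incident_falls ~ fall-history level` under the NB2 model
#' (variance `mu + mu^2/theta`, log link) by maximum likelihood via
#' [MASS::glm.nb()], optionally with a `log(exposure_years)` offset for
#' cohorts with variable follow-up.  The linear predictor is
#' `alpha + beta[level] (+ log exposure)`; `exp(alpha)` is the baseline
#' fall rate per person-year and `exp(beta)` the per-level rate ratios.
#'
#' Factor levels with no participants are dropped from the fit with a
#' warning and recorded in the returned model, so downstream pooling can
#' skip (never impute) them.  Fixing `theta` switches to a
#' [stats::glm()] fit with a `MASS::negative.binomial(theta)` family
#' (useful for Poisson-limit checks with large `theta`); `se_theta` is then
#' `NA`.
#'
#' @param table Cohort table with no missing model variables (apply
#'   [filter_complete_cases()] first).
#' @param use_offset Include the `log(exposure_years)` person-time offset?
#'   Use `TRUE` for cohorts with variable follow-up.
#' @param label Model label carried into downstream outputs.
#' @param theta Optional fixed dispersion; default `NULL` estimates
#'   `theta` jointly by ML.
#' @param epsilon,maxit Convergence tolerance (relative deviance change) and
#'   iteration cap of the inner IRLS fits.
#'
#' @return A `fall_rate_model`: `alpha`/`se_alpha` (log baseline rate),
#'   `beta`/`se_beta` (named log rate ratios for levels 1--5+, `NA` where a
#'   level was dropped), the 6x6 coefficient covariance `vcov` (rows of
#'   dropped levels `NA`), `theta`/`se_theta`, `n_fitted`, `converged`,
#'   `offset_used`, `dropped_levels`.
#' @export
#' @examples
#' tab <- generate_cohort(default_cohort_specs(seed = 7)$gerico)
#' fit <- fit_negative_binomial(tab, label = "gerico")
#' rate_ratio_table(fit)
fit_negative_binomial <- function(table, use_offset = FALSE, label = "model",
                                  theta = NULL, epsilon = 1e-10,
                                  maxit = 200L) {
  vars <- c("prior_falls_12m", "incident_falls", "exposure_years")
  if (anyNA(table[vars]))
    stop("table contains missing model variables; apply ",
         "filter_complete_cases() first", call. = FALSE)
  if (any(table$exposure_years <= 0))
    stop("exposure_years must be positive", call. = FALSE)

  all_levels <- prior_fall_levels()
  lvl <- factor(categorize_prior_falls(table$prior_falls_12m),
                levels = all_levels)
  dropped <- all_levels[tabulate(lvl, 6L) == 0L]
  if (length(dropped)) {
    warning("fall-history level(s) with no participants dropped from fit: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    lvl <- droplevels(lvl)
  }
  dat <- data.frame(y = table$incident_falls, lvl = lvl,
                    off = log(table$exposure_years))
  # one represented level collapses to an intercept-only fit
  rhs <- if (nlevels(lvl) > 1L) "lvl" else "1"
  fml <- stats::as.formula(
    paste("y ~", rhs, if (use_offset) "+ offset(off)" else ""))
  environment(fml) <- environment()
  ctrl <- glm.control(epsilon = epsilon, maxit = maxit)

  fit <- tryCatch(
    if (is.null(theta)) {
      MASS::glm.nb(fml, data = dat, control = ctrl)
    } else {
      glm(fml, data = dat, family = MASS::negative.binomial(theta),
          control = ctrl)
    },
    error = function(e) {
      stop("negative-binomial fit failed (possibly degenerate outcomes, ",
           "e.g. all zero, leaving theta unidentifiable): ",
           conditionMessage(e), call. = FALSE)
    })

  cf <- coef(fit)
  vc_fit <- vcov(fit)
  kept <- levels(lvl)
  par_names <- c("alpha", paste0("b", all_levels[-1]))
  fit_names <- c("(Intercept)", paste0("lvl", kept[-1], recycle0 = TRUE))
  map <- match(fit_names, names(cf))
  stopifnot(!anyNA(map))
  kept_par <- c("alpha", paste0("b", kept[-1], recycle0 = TRUE))

  beta <- setNames(rep(NA_real_, 5L), par_names[-1])
  se_all <- setNames(rep(NA_real_, 6L), par_names)
  vc <- matrix(NA_real_, 6L, 6L, dimnames = list(par_names, par_names))
  est <- setNames(cf[map], kept_par)
  se_all[kept_par] <- sqrt(diag(vc_fit)[map])
  vc[kept_par, kept_par] <- vc_fit[map, map]
  beta[intersect(names(beta), kept_par)] <-
    est[intersect(names(beta), kept_par)]

  converged <- isTRUE(fit$converged) && is.null(fit$th.warn)
  structure(
    list(label = label,
         reference_level = "0",
         alpha = unname(est["alpha"]),
         se_alpha = unname(se_all["alpha"]),
         beta = beta,
         se_beta = se_all[-1],
         vcov = vc,
         theta = if (is.null(theta)) fit$theta else theta,
         se_theta = if (is.null(theta)) fit$SE.theta else NA_real_,
         n_fitted = nrow(dat),
         converged = converged,
         offset_used = use_offset,
         dropped_levels = dropped),
    class = "fall_rate_model")
}

#' @export
print.fall_rate_model <- function(x, ...) {
  cat("Negative-binomial fall-rate model:", x$label, "\n")
  cat(sprintf("  n = %d, theta = %.3f%s, offset %s, %s\n",
              x$n_fitted, x$theta,
              if (is.na(x$se_theta)) " (fixed)"
              else sprintf(" (SE %.3f)", x$se_theta),
              if (x$offset_used) "on" else "off",
              if (x$converged) "converged" else "NOT converged"))
  print(rate_ratio_table(x), digits = 3)
  if (length(x$dropped_levels))
    cat("  dropped levels:", paste(x$dropped_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Baseline rate and rate ratios with confidence intervals
#'
#' Exponentiates the model coefficients: the reference row reports the
#' baseline fall rate per person-year, `exp(alpha)`, and the remaining rows
#' the per-level rate ratios `exp(beta)`, each with a Wald interval
#' `exp(estimate +/- z * SE)` on the response scale.
#'
#' @param model A `fall_rate_model` (or the pooled model from
#'   [meta_analyze_models()]).
#' @param z Normal quantile of the interval; 1.96 gives 95% limits.
#' @return `data.frame` with columns `term`, `level`, `estimate`,
#'   `ci_low`, `ci_high`.
#' @export
rate_ratio_table <- function(model, z = 1.96) {
  est <- c(model$alpha, model$beta)
  se <- c(model$se_alpha, model$se_beta)
  data.frame(
    term = c("baseline_rate", paste0("rate_ratio_", names(model$beta))),
    level = prior_fall_levels(),
    estimate = exp(est),
    ci_low = exp(est - z * se),
    ci_high = exp(est + z * se),
    row.names = NULL)
}

#' Expected number of falls for a participant profile
#'
#' `exp(alpha + beta[level]) * exposure_years`, the NB2 mean for a
#' participant with the given fall-history level followed for
#' `exposure_years`.
#'
#' @param model A `fall_rate_model`.
#' @param level Fall-history level(s), in `{"0","1","2","3","4","5+"}`.
#' @param exposure_years Positive follow-up time(s) in years.
#' @return Expected fall counts (non-negative numeric).
#' @export
#' @examples
#' tab <- generate_cohort(default_cohort_specs(seed = 7)$kfps)
#' m <- fit_negative_binomial(tab, label = "kfps")
#' predict_expected_falls(m, "5+", 1)
predict_expected_falls <- function(model, level, exposure_years) {
  if (any(exposure_years <= 0))
    stop("exposure_years must be positive", call. = FALSE)
  level <- as.character(level)
  unknown <- setdiff(unique(level), prior_fall_levels())
  if (length(unknown))
    stop("unknown fall-history level(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  eta <- model$alpha + beta_term(model, level)
  if (anyNA(eta)) {
    bad <- unique(level[is.na(beta_term(model, level))])
    stop("model '", model$label, "' cannot predict for level(s) ",
         paste(bad, collapse = ", "),
         if (length(intersect(bad, model$dropped_levels)))
           " (dropped during fitting: no participants at that level)" else "",
         call. = FALSE)
  }
  exp(eta) * exposure_years
}

# log rate-ratio term for a vector of levels; 0 for the reference level.
beta_term <- function(model, level) {
  b <- setNames(c(0, model$beta), prior_fall_levels())
  unname(b[level])
}

# Linear predictor on the link scale, including the log person-time offset:
# alpha + beta[level] + log(exposure).  Used by calibration and rootograms.
linear_predictor <- function(model, table) {
  lev <- categorize_prior_falls(table$prior_falls_12m)
  eta <- model$alpha + beta_term(model, lev) + log(table$exposure_years)
  if (anyNA(eta))
    stop("model '", model$label,
         "' cannot form a linear predictor for every participant ",
         "(missing data or fall-history level absent from the fit)",
         call. = FALSE)
  eta
}

#' Serialize a fitted model to JSON
#'
#' Round-trips every field of a `fall_rate_model` (coefficients, standard
#' errors, covariance, dispersion, metadata) through a plain JSON object.
#'
#' @param model A `fall_rate_model`.
#' @param path File path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` the reconstructed model.
#' @export
write_model_json <- function(model, path) {
  x <- unclass(model)
  x$vcov <- unname(as.matrix(x$vcov))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  par_names <- c("alpha", paste0("b", prior_fall_levels()[-1]))
  x$beta <- setNames(as.numeric(x$beta), par_names[-1])
  x$se_beta <- setNames(as.numeric(x$se_beta), par_names[-1])
  vc <- x$vcov
  if (is.list(vc)) vc <- do.call(rbind, lapply(vc, as.numeric))
  x$vcov <- matrix(as.numeric(vc), 6L, 6L,
                   dimnames = list(par_names, par_names))
  x$dropped_levels <- as.character(x$dropped_levels %||% character())
  structure(x, class = "fall_rate_model")
}
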