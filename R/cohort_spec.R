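#' Specify a synthetic cohort
#'
#' A cohort spec holds the generative parameters of one synthetic cohort:
#' the marginal distribution of the fall-history factor, the baseline fall
#' rate (falls per person-year, `exp(alpha)` of the NB2 model), the per-level
#' rate ratios, the NB2 dispersion `theta` (variance `mu + mu^2/theta`), and
#' the follow-up exposure model.
#'
#' @param label Cohort name used in ids and output files.
#' @param n Number of participants (positive integer).
#' @param category_probs Probabilities of the six fall-history levels
#'   `0, 1, 2, 3, 4, 5+`; must be non-negative and sum to 1 (within 1e-12).
#' @param baseline_rate Falls per person-year for the reference level.
#' @param rate_ratios Length-6 vector of rate ratios; the first entry
#'   (level 0) must equal 1 exactly.
#' @param theta NB2 dispersion; larger values mean less overdispersion.
#' @param exposure Exposure model: `list(model = "fixed", value = 1)` for a
#'   common follow-up, or `list(model = "uniform", min = , max = )` for
#'   variable follow-up in years (an offset is then needed when fitting).
#' @param tail_geometric_p Success probability of the geometric draw used to
#'   assign a raw prior-fall count inside the open-ended `5+` level (raw
#'   count = 5 + geometric); only the level enters the model, so this is
#'   cosmetic.
#' @param seed Integer seed making [generate_cohort()] reproducible.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [default_cohort_specs()], [generate_cohort()],
#'   [read_cohort_spec()]
#' @export
#' @examples
#' spec <- cohort_spec("toy", n = 100, category_probs = c(1, 0, 0, 0, 0, 0),
#'                     baseline_rate = 0.5, rate_ratios = rep(1, 6),
#'                     theta = 1, seed = 1)
#' head(generate_cohort(spec))
cohort_spec <- function(label, n, category_probs, baseline_rate, rate_ratios,
                        theta,
                        exposure = list(model = "fixed", value = 1),
                        tail_geometric_p = 0.5, seed = 1L) {
  spec <- structure(
    list(label = as.character(label), n = n,
         category_probs = as.numeric(category_probs),
         baseline_rate = baseline_rate,
         rate_ratios = as.numeric(rate_ratios), theta = theta,
         exposure = exposure, tail_geometric_p = tail_geometric_p,
         seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
      stop("invalid cohort spec: 'n' must be a positive integer", call. = FALSE)
    if (length(category_probs) != 6L || any(category_probs < 0))
      stop("invalid cohort spec: 'category_probs' must be 6 non-negative values",
           call. = FALSE)
    if (abs(sum(category_probs) - 1) > 1e-12)
      stop("invalid cohort spec: 'category_probs' must sum to 1 (within 1e-12)",
           call. = FALSE)
    if (!is.numeric(baseline_rate) || baseline_rate <= 0)
      stop("invalid cohort spec: 'baseline_rate' must be > 0", call. = FALSE)
    if (length(rate_ratios) != 6L || any(rate_ratios <= 0))
      stop("invalid cohort spec: 'rate_ratios' must be 6 positive values",
           call. = FALSE)
    if (rate_ratios[1] != 1)
      stop("invalid cohort spec: 'rate_ratios[1]' (level 0) must equal 1",
           call. = FALSE)
    if (!is.numeric(theta) || theta <= 0)
      stop("invalid cohort spec: 'theta' must be > 0", call. = FALSE)
    if (!is.numeric(tail_geometric_p) || tail_geometric_p <= 0 ||
        tail_geometric_p > 1)
      stop("invalid cohort spec: 'tail_geometric_p' must be in (0, 1]",
           call. = FALSE)
    if (!is.list(exposure) || is.null(exposure$model))
      stop("invalid cohort spec: 'exposure' must name a model", call. = FALSE)
    if (identical(exposure$model, "fixed")) {
      if (is.null(exposure$value) || exposure$value <= 0)
        stop("invalid cohort spec: fixed exposure value must be > 0",
             call. = FALSE)
    } else if (identical(exposure$model, "uniform")) {
      if (is.null(exposure$min) || is.null(exposure$max) ||
          exposure$min <= 0 || exposure$max < exposure$min)
        stop("invalid cohort spec: uniform exposure needs 0 < min <= max",
             call. = FALSE)
    } else {
      stop("invalid cohort spec: exposure model must be 'fixed' or 'uniform'",
           call. = FALSE)
    }
  })
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$label, "\n")
  cat("  n =", x$n, "  baseline rate =", x$baseline_rate,
      "falls/person-year  theta =", x$theta, "\n")
  cat("  level probs:", paste(sprintf("%s=%.4g", prior_fall_levels(),
                                      x$category_probs), collapse = " "), "\n")
  cat("  rate ratios:", paste(sprintf("%.3g", x$rate_ratios), collapse = " "),
      "\n")
  if (identical(x$exposure$model, "fixed")) {
    cat("  exposure: fixed", x$exposure$value, "year(s)\n")
  } else {
    cat("  exposure: uniform(", x$exposure$min, ",", x$exposure$max,
        ") years\n")
  }
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Default specs emulating the three source cohorts
#'
#' Returns specs for three synthetic cohorts shaped like the Geneva Retirees
#' Cohort (GERICO), the Swiss CHEF Trial (SCT) and the Kuopio Fall Prevention
#' Study (KFPS): sample sizes 630 / 370 / 855, baseline rates 0.43 / 0.83 /
#' 0.61 falls per person-year, published per-level rate ratios, and NB2
#' dispersions 1.06 / 0.66 / 1.18.  The SCT-like cohort has variable
#' follow-up, uniform between one month and one year, so its model is fitted
#' with a person-time offset; the other two have a fixed 12-month window.
#'
#' The fall-history level probabilities are not published; the defaults are
#' chosen so the mean prior-fall count matches the reported cohort means
#' (1.03 / 1.45 / 0.73) given the within-`5+` rule, and should be read as
#' plausible approximations, not study values.
#'
#' @param seed Global seed; each cohort gets its own substream derived from
#'   it, so the three cohorts are independent but jointly reproducible.
#'
#' @return Named list of three [cohort_spec()] objects
#'   (`gerico`, `sct`, `kfps`).
#' @export
#' @examples
#' specs <- default_cohort_specs(seed = 1)
#' specs$gerico$n
default_cohort_specs <- function(seed = 20240327L) {
  list(
    gerico = cohort_spec(
      label = "gerico", n = 630L,
      category_probs = c(0.56, 0.20, 0.10, 0.05, 0.03, 0.06),
      baseline_rate = 0.43,
      rate_ratios = c(1, 1.64, 1.13, 2.55, 2.33, 10.02),
      theta = 1.06,
      exposure = list(model = "fixed", value = 1),
      seed = substream_seed(seed, 1L)),
    sct = cohort_spec(
      label = "sct", n = 370L,
      category_probs = c(0.4133333333333333, 0.25, 0.12, 0.08, 0.05,
                         0.0866666666666667),
      baseline_rate = 0.83,
      rate_ratios = c(1, 1.00, 1.07, 2.18, 3.09, 7.39),
      theta = 0.66,
      exposure = list(model = "uniform", min = 1 / 12, max = 1),
      seed = substream_seed(seed, 2L)),
    kfps = cohort_spec(
      label = "kfps", n = 855L,
      category_probs = c(0.6483333333333333, 0.18, 0.08, 0.04, 0.02,
                         0.0316666666666667),
      baseline_rate = 0.61,
      rate_ratios = c(1, 1.46, 1.65, 2.98, 6.24, 7.40),
      theta = 1.18,
      exposure = list(model = "fixed", value = 1),
      seed = substream_seed(seed, 3L)))
}

#' Read or write a cohort spec as YAML
#'
#' Specs serialize to a flat YAML mapping (`label`, `n`, `category_probs`,
#' `baseline_rate`, `rate_ratios`, `theta`, `exposure`, `tail_geometric_p`,
#' `seed`).  Three ready-made spec files ship with the package under
#' `system.file("specs", package = "fallmeta")`.
#'
#' @param path File path.
#' @return `read_cohort_spec()` returns a validated [cohort_spec()];
#'   `write_cohort_spec()` returns `path` invisibly.
#' @export
#' @examples
#' spec <- read_cohort_spec(system.file("specs", "gerico.yaml",
#'                                      package = "fallmeta"))
#' spec$n
read_cohort_spec <- function(path) {
  if (!file.exists(path))
    stop("cohort spec file does not exist: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  cohort_spec(label = raw$label, n = raw$n,
              category_probs = unlist(raw$category_probs),
              baseline_rate = raw$baseline_rate,
              rate_ratios = unlist(raw$rate_ratios),
              theta = raw$theta,
              exposure = raw$exposure,
              tail_geometric_p = raw$tail_geometric_p %||% 0.5,
              seed = raw$seed %||% 1L)
}

#' @rdname read_cohort_spec
#' @param spec A [cohort_spec()].
#' @export
write_cohort_spec <- function(spec, path) {
  validate_cohort_spec(spec)
  yaml::write_yaml(unclass(spec), path, precision = 15L)
  invisible(path)
}
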