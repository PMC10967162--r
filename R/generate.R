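#' Generate a synthetic participant-level cohort
#'
#' Draws `spec$n` participants.  Each participant gets a fall-history level
#' from `category_probs`, a raw prior-fall count consistent with that level
#' (levels 0--4 map to themselves; level `5+` draws 5 + geometric), an
#' exposure in person-years from the spec's exposure model, and an incident
#' fall count from the NB2 gamma-Poisson mixture: the Poisson rate
#' `lambda = baseline_rate * rate_ratio[level] * exposure` is multiplied by
#' a gamma deviate with shape `theta` and mean 1 before the Poisson draw,
#' giving marginal mean `lambda` and variance `lambda + lambda^2 / theta`
#' (the parameterization of `MASS::glm.nb`).
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` with columns `id`, `prior_falls_12m`,
#'   `incident_falls`, `exposure_years`; exactly `spec$n` rows, reproducible
#'   from `spec$seed`.
#' @export
#' @examples
#' spec <- default_cohort_specs(seed = 7)$gerico
#' tab <- generate_cohort(spec)
#' mean(tab$incident_falls)
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  withr::with_seed(spec$seed, {
    n <- spec$n
    lvl <- sample.int(6L, n, replace = TRUE, prob = spec$category_probs)
    prior <- lvl - 1L
    tail <- lvl == 6L
    if (any(tail))
      prior[tail] <- 5L + rgeom(sum(tail), prob = spec$tail_geometric_p)
    exposure <- switch(spec$exposure$model,
      fixed   = rep(spec$exposure$value, n),
      uniform = runif(n, spec$exposure$min, spec$exposure$max))
    lambda <- spec$baseline_rate * spec$rate_ratios[lvl] * exposure
    frailty <- rgamma(n, shape = spec$theta, rate = spec$theta)
    falls <- rpois(n, lambda * frailty)
    data.frame(
      id = sprintf("%s-%05d", spec$label, seq_len(n)),
      prior_falls_12m = as.integer(prior),
      incident_falls = as.integer(falls),
      exposure_years = exposure,
      stringsAsFactors = FALSE)
  })
}

#' Blank out incident-fall outcomes at random
#'
#' Sets `incident_falls` to missing for `round(fraction * nrow(table))`
#' randomly chosen rows, to exercise complete-case handling downstream.
#'
#' @param table A cohort table (see [generate_cohort()]).
#' @param fraction Fraction of rows to blank, in `[0, 1]`.
#' @param seed Integer seed; the same seed reproduces the same missing rows.
#' @return The table with the chosen outcomes set to `NA`.
#' @export
inject_missingness <- function(table, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("'fraction' must be a single value in [0, 1]", call. = FALSE)
  n_miss <- round(fraction * nrow(table))
  if (n_miss > 0) {
    idx <- withr::with_seed(seed, sample.int(nrow(table), n_miss))
    table$incident_falls[idx] <- NA_integer_
  }
  table
}

#' Read or write a cohort table as CSV
#'
#' The on-disk schema is `id,prior_falls_12m,incident_falls,exposure_years`
#' with missing values encoded as empty fields.
#'
#' @param path File path.
#' @return `read_cohort_csv()` returns the cohort `data.frame`;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  tab <- read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                  colClasses = c(id = "character"))
  required <- c("id", "prior_falls_12m", "incident_falls", "exposure_years")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- !is.na(tab$exposure_years) & tab$exposure_years <= 0
  if (any(bad))
    stop("cohort CSV has non-positive exposure_years", call. = FALSE)
  tab[required]
}

#' @rdname read_cohort_csv
#' @param table A cohort table.
#' @export
write_cohort_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
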