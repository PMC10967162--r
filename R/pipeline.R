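#' Published per-cohort coefficient table
#'
#' Loads the published first-stage coefficient table bundled with the
#' package: per cohort (GERICO, SCT, KFPS) the baseline fall rate, the five
#' fall-history rate ratios and the NB2 dispersion `theta`, each with its
#' 95% interval, plus the published overall column and heterogeneity
#' measures for comparison.  Rate rows are pooled on the log scale,
#' `theta` on the linear scale (column `scale`).
#'
#' @param path CSV path; defaults to the bundled fixture.
#' @return `data.frame`, one row per coefficient.
#' @seealso [reproduce_published_table()]
#' @export
published_table <- function(path = system.file("extdata",
                                                "published_coefficients.csv",
                                                package = "fallmeta")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("term", "scale",
              t(outer(c("gerico", "sct", "kfps"), c("", "_lo", "_hi"),
                      paste0)))
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("published table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (ch in c("gerico", "sct", "kfps")) {
    bad <- tab[[paste0(ch, "_lo")]] > tab[[ch]] |
      tab[[ch]] > tab[[paste0(ch, "_hi")]]
    if (any(bad))
      stop("published table: interval ordering violated for cohort '", ch,
           "', row(s) ", paste(tab$term[bad], collapse = ", "),
           call. = FALSE)
  }
  tab
}

#' Re-derive the overall column from published per-cohort estimates
#'
#' Runs the second stage of the two-stage meta-analysis on the published
#' first-stage values alone: each coefficient's three cohort estimates are
#' moved to the analysis scale ([log_scale_from_ci()] for rates and rate
#' ratios; linear-scale SEs from the symmetric `theta` intervals), the
#' between-study variance is estimated by REML, and the coefficients are
#' pooled with inverse-variance random-effects weights.  The report
#' compares each recomputed overall estimate, `tau2` and Higgins `I2`
#' against the published values and flags any overall estimate deviating
#' by more than `fail_above` on the response scale as `FAIL`.
#'
#' @param published Published table in the layout of [published_table()].
#' @param fail_above Absolute response-scale deviation above which a row is
#'   flagged.
#' @return A `published_table_report` data frame: per coefficient the
#'   recomputed estimate/CI, `tau2`, `i2`, the published values, absolute
#'   deviations and a `pass` flag.
#' @export
#' @examples
#' rep <- reproduce_published_table()
#' rep[, c("term", "estimate", "published", "deviation", "pass")]
reproduce_published_table <- function(published = published_table(),
                                      fail_above = 0.05) {
  rows <- lapply(seq_len(nrow(published)), function(i) {
    r <- published[i, ]
    point <- c(r$gerico, r$sct, r$kfps)
    lo <- c(r$gerico_lo, r$sct_lo, r$kfps_lo)
    hi <- c(r$gerico_hi, r$sct_hi, r$kfps_hi)
    studies <- c("gerico", "sct", "kfps")
    if (identical(r$scale, "log")) {
      est <- log_scale_from_ci(point, lo, hi, study = studies)
      res <- meta_analyze(est$y, est$se, study = studies)
      tr <- exp
    } else {
      se <- (hi - lo) / (2 * 1.96)
      res <- meta_analyze(point, se, study = studies)
      tr <- identity
    }
    data.frame(
      term = r$term,
      estimate = tr(res$mu),
      ci_low = tr(res$ci95[["low"]]),
      ci_high = tr(res$ci95[["high"]]),
      tau2 = res$tau2,
      i2 = res$i2,
      published = r$overall,
      published_lo = r$overall_lo,
      published_hi = r$overall_hi,
      published_tau2 = r$tau2,
      published_i2 = r$i2,
      deviation = abs(tr(res$mu) - r$overall),
      pass = abs(tr(res$mu) - r$overall) <= fail_above)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("published_table_report", "data.frame")
  out
}

#' @export
`[.published_table_report` <- function(x, ...) {
  y <- NextMethod()
  if (is.data.frame(y)) class(y) <- "data.frame"
  y
}

#' @export
print.published_table_report <- function(x, ...) {
  cat("Second-stage reproduction of the published overall column\n")
  d <- as.data.frame(x)
  d$estimate <- sprintf("%.3f (%.3f-%.3f)", d$estimate, d$ci_low, d$ci_high)
  d$published <- sprintf("%.2f (%.2f-%.2f)", d$published, d$published_lo,
                         d$published_hi)
  d$status <- ifelse(d$pass, "PASS", "FAIL")
  print(d[c("term", "estimate", "published", "deviation", "tau2", "i2",
            "status")], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Configure the end-to-end analysis pipeline
#'
#' @param specs Named list of [cohort_spec()]s to simulate (default: the
#'   three study-like specs re-seeded from `seed`), or `NULL` when
#'   `cohort_csvs` is given.
#' @param cohort_csvs Optional named character vector of cohort CSV paths;
#'   overrides simulation.
#' @param seed Global seed; simulation substreams derive from it.
#' @param output_dir Directory for all run artifacts.
#' @param use_offset Named logical: person-time offset per cohort.  Cohorts
#'   not named default to `FALSE`; simulated cohorts with a variable
#'   exposure model default to `TRUE`.
#' @param theta_scale Pooling scale for `theta` (see
#'   [meta_analyze_models()]).
#' @param rootogram_K Tail threshold of the rootograms.
#' @param missing_fraction Fraction of outcomes to blank before the
#'   complete-case filter (exercises the filtering stage; default 0).
#' @param figures Write PNG figures?  Skipped automatically (with a log
#'   line) when no PNG device is available.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(specs = NULL, cohort_csvs = NULL, seed = 1L,
                            output_dir = tempfile("fallmeta_run_"),
                            use_offset = NULL,
                            theta_scale = c("linear", "log"),
                            rootogram_K = 20L,
                            missing_fraction = 0,
                            figures = TRUE) {
  theta_scale <- match.arg(theta_scale)
  if (is.null(specs) && is.null(cohort_csvs))
    specs <- default_cohort_specs(seed = seed)
  if (!is.null(cohort_csvs)) {
    missing_files <- cohort_csvs[!file.exists(cohort_csvs)]
    if (length(missing_files))
      stop("cohort CSV path(s) do not exist: ",
           paste(missing_files, collapse = ", "), call. = FALSE)
  }
  structure(
    list(specs = specs, cohort_csvs = cohort_csvs, seed = as.integer(seed),
         output_dir = output_dir, use_offset = use_offset,
         theta_scale = theta_scale, rootogram_K = rootogram_K,
         missing_fraction = missing_fraction, figures = figures),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: top-level `seed`, `output_dir`,
#' `theta_scale`, `rootogram_K`, `missing_fraction`, `figures`, plus either
#' `spec_files` (paths to cohort-spec YAMLs) or `cohort_csvs` (paths to
#' cohort tables), and an optional `use_offset` mapping.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("pipeline config file does not exist: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  specs <- NULL
  if (!is.null(raw$spec_files)) {
    specs <- lapply(raw$spec_files, read_cohort_spec)
    names(specs) <- vapply(specs, function(s) s$label, character(1))
  }
  pipeline_config(
    specs = specs,
    cohort_csvs = unlist(raw$cohort_csvs),
    seed = raw$seed %||% 1L,
    output_dir = raw$output_dir %||% tempfile("fallmeta_run_"),
    use_offset = unlist(raw$use_offset),
    theta_scale = raw$theta_scale %||% "linear",
    rootogram_K = raw$rootogram_K %||% 20L,
    missing_fraction = raw$missing_fraction %||% 0,
    figures = raw$figures %||% TRUE)
}

#' Run the full two-stage analysis end-to-end
#'
#' Orchestrates the complete pipeline: obtain cohorts (simulate from specs
#' or read CSVs), complete-case filter, fit the first-stage NB2 models,
#' pool them into the overall model, cross-validate all models on all
#' cohorts (mean absolute prediction error), compute pairwise
#' calibration-in-the-large constants, and build rootograms of every
#' cohort under the overall model.  All artifacts are written under
#' `config$output_dir`:
#' model JSONs (one per cohort plus `overall`), `meta_table.csv`,
#' `mae_matrix.csv`, `recalibration_constants.csv`, rootogram CSVs,
#' figures (when enabled and a PNG device exists), a per-stage
#' `pipeline.log`, and `manifest.json` recording the seed, configuration
#' hash and package version.  The run is deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the tables, models, `fall_meta` object,
#'   MAE matrix, recalibration matrix, rootograms and artifact paths.
#' @export
#' @examples
#' \donttest{
#' res <- run_full_pipeline(pipeline_config(seed = 42, figures = FALSE))
#' res$mae_matrix
#' }
run_full_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "pipeline.log")
  log_lines <- character()
  log_msg <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage '", name, "'")),
                 log_path)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- stage: cohorts -----------------------------------------------------
  tables <- stage("cohorts", {
    if (!is.null(config$cohort_csvs)) {
      tabs <- lapply(config$cohort_csvs, read_cohort_csv)
      names(tabs) <- names(config$cohort_csvs) %||%
        tools::file_path_sans_ext(basename(config$cohort_csvs))
      tabs
    } else {
      tabs <- lapply(config$specs, generate_cohort)
      if (config$missing_fraction > 0)
        tabs <- lapply(seq_along(tabs), function(i)
          inject_missingness(tabs[[i]], config$missing_fraction,
                             seed = substream_seed(config$seed, 100L + i)))
      names(tabs) <- vapply(config$specs, function(s) s$label, character(1))
      tabs
    }
  })
  for (nm in names(tables))
    log_msg("cohort '", nm, "': ", nrow(tables[[nm]]), " rows")

  # --- stage: complete cases ----------------------------------------------
  tables <- stage("complete_cases", lapply(tables, function(tab)
    suppressMessages(filter_complete_cases(tab))))
  for (nm in names(tables))
    log_msg("cohort '", nm, "': dropped ",
            attr(tables[[nm]], "n_dropped"), " incomplete rows, ",
            nrow(tables[[nm]]), " analysed")

  # --- stage: first-stage fits --------------------------------------------
  offsets <- vapply(names(tables), function(nm) {
    if (!is.null(config$use_offset) && nm %in% names(config$use_offset))
      isTRUE(config$use_offset[[nm]])
    else if (!is.null(config$specs) && nm %in% names(config$specs))
      identical(config$specs[[nm]]$exposure$model, "uniform")
    else FALSE
  }, logical(1))
  models <- stage("fit", lapply(names(tables), function(nm)
    fit_negative_binomial(tables[[nm]], use_offset = offsets[[nm]],
                          label = nm)))
  names(models) <- names(tables)
  for (m in models)
    log_msg("model '", m$label, "': theta = ", signif(m$theta, 4),
            ", offset ", if (m$offset_used) "on" else "off")

  # --- stage: meta-analysis -----------------------------------------------
  fm <- stage("meta", meta_analyze_models(models,
                                          theta_scale = config$theta_scale))
  log_msg("pooled overall baseline rate: ",
          signif(exp(fm$overall$alpha), 4), " falls/person-year")

  # --- stage: validation ---------------------------------------------------
  all_models <- c(models, list(overall = fm$overall))
  mae <- stage("validate", cross_validation_matrix(all_models, tables))

  # --- stage: recalibration ------------------------------------------------
  recal <- stage("recalibrate", {
    out <- matrix(NA_real_, length(all_models), length(tables),
                  dimnames = list(names(all_models), names(tables)))
    for (m in names(all_models))
      for (d in names(tables))
        out[m, d] <- calibration_in_the_large(all_models[[m]],
                                              tables[[d]])$alpha_new
    out
  })

  # --- stage: rootograms ---------------------------------------------------
  roots <- stage("rootogram", lapply(tables, function(tab)
    rootogram(fm$overall, tab, K = config$rootogram_K)))

  # --- stage: artifacts ----------------------------------------------------
  paths <- stage("write", {
    p <- list()
    for (m in names(all_models))
      p[[paste0("model_", m)]] <- write_model_json(
        all_models[[m]], file.path(config$output_dir,
                                   paste0("model_", m, ".json")))
    meta_csv <- file.path(config$output_dir, "meta_table.csv")
    write.csv(meta_result_table(fm), meta_csv, row.names = FALSE)
    p$meta <- meta_csv
    mae_csv <- file.path(config$output_dir, "mae_matrix.csv")
    write.csv(as.data.frame(mae), mae_csv)
    p$mae <- mae_csv
    recal_csv <- file.path(config$output_dir, "recalibration_constants.csv")
    write.csv(as.data.frame(recal), recal_csv)
    p$recalibration <- recal_csv
    for (nm in names(roots)) {
      rp <- file.path(config$output_dir,
                      paste0("rootogram_overall_", nm, ".csv"))
      write.csv(as.data.frame(roots[[nm]]), rp, row.names = FALSE)
      p[[paste0("rootogram_", nm)]] <- rp
    }
    if (isTRUE(config$figures)) {
      if (capabilities("png")) {
        fp <- file.path(config$output_dir, "forest.png")
        ggplot2::ggsave(fp, plot_forest(fm), width = 8, height = 6,
                        dpi = 150)
        p$forest_figure <- fp
        for (nm in names(roots)) {
          rp <- file.path(config$output_dir,
                          paste0("rootogram_overall_", nm, ".png"))
          ggplot2::ggsave(rp, plot(roots[[nm]]), width = 8, height = 4,
                          dpi = 150)
          p[[paste0("rootogram_fig_", nm)]] <- rp
        }
      } else {
        log_msg("figures requested but no PNG device available; skipped")
      }
    }
    p
  })

  manifest <- list(
    package = "fallmeta",
    package_version = as.character(utils::packageVersion("fallmeta")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_md5 = config_hash(config),
    cohorts = lapply(tables, nrow),
    artifacts = names(paths))
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  log_msg("run complete; ", length(paths), " artifacts in ",
          config$output_dir)
  writeLines(log_lines, log_path)

  invisible(list(tables = tables, models = models, meta = fm,
                 mae_matrix = mae, recalibration = recal,
                 rootograms = roots, paths = paths,
                 manifest = manifest_path, log = log_path))
}

# Stable md5 fingerprint of a configuration (serialized without the
# environment-dependent output_dir).
config_hash <- function(config) {
  x <- unclass(config)
  x$output_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}
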