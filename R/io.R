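# Cohort CSV I/O, pipeline configuration and the end-to-end pipeline.

#' Read and validate a long-format cohort CSV
#'
#' One row per subject x timepoint. Required columns: `subject_id`,
#' `timepoint` (`"T0"`/`"T6"`), `age`. Methylation columns (one per clock
#' gene) are validated to \[0, 100\] when present. Every subject must have
#' exactly one row per timepoint (complete pairs); violations are
#' reported with the offending subjects or rows.
#'
#' @param path CSV path (UTF-8, header row).
#' @param require_methylation If `TRUE`, the five clock gene columns must
#'   be present.
#' @return Validated data frame.
#' @export
read_cohort_csv <- function(path, require_methylation = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(data, require_methylation = require_methylation)
  data
}

#' Validate a cohort data frame
#'
#' @param data Long cohort data frame.
#' @param require_methylation Require the five clock gene columns.
#' @return `data`, invisibly; errors describe offending rows/columns.
#' @export
validate_cohort <- function(data, require_methylation = TRUE) {
  need <- c("subject_id", "timepoint", "age")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  bad_tp <- which(!data$timepoint %in% c("T0", "T6"))
  if (length(bad_tp) > 0)
    stop("invalid timepoint at row(s) ", paste(utils::head(bad_tp, 5), collapse = ", "),
         "; expected 'T0' or 'T6'")
  if (any(!is.finite(data$age)) || any(data$age <= 0))
    stop("chronological age must be finite and positive; offending row(s): ",
         paste(utils::head(which(!is.finite(data$age) | data$age <= 0), 5),
               collapse = ", "))
  .check_long_pairs(data)
  meth_cols <- intersect(.CLOCK_GENES, names(data))
  if (require_methylation && length(meth_cols) < length(.CLOCK_GENES))
    stop("missing methylation column(s): ",
         paste(setdiff(.CLOCK_GENES, names(data)), collapse = ", "))
  for (g in meth_cols) {
    bad <- which(!is.finite(data[[g]]) | data[[g]] < 0 | data[[g]] > 100)
    if (length(bad) > 0)
      stop("methylation '", g, "' outside [0, 100] at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(data)
}

#' Pipeline configuration
#'
#' @param covariates Covariate columns for the adjusted and interaction
#'   models (Table-3/4-style batteries).
#' @param table1_variables Variables for the paired summary table;
#'   defaults to the covariates plus age, DNAm age and acceleration.
#' @param marginal Named numeric vector: covariate = fixed value for
#'   marginal means (e.g. `c(igf1 = 120)`).
#' @param clock_file Optional path to a clock JSON; `NULL` uses the
#'   built-in clock.
#' @param scope Residual-regression scope, `"pooled"` or
#'   `"baseline_only"`.
#' @param normality_overrides Named character vector forcing
#'   `"paired_t"` or `"wilcoxon"` per variable.
#' @param df_method Wald df method for mixed models.
#' @param conf_level CI level in (0, 1).
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic given its input data).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(covariates = c("igf1", "glucose", "insulin",
                                           "homa_ir", "height", "hv", "hba1c"),
                            table1_variables = NULL,
                            marginal = c(igf1 = 120),
                            clock_file = NULL,
                            scope = c("pooled", "baseline_only"),
                            normality_overrides = NULL,
                            df_method = c("residual", "satterthwaite"),
                            conf_level = 0.95,
                            seed = 1L) {
  scope <- match.arg(scope)
  df_method <- match.arg(df_method)
  if (conf_level <= 0 || conf_level >= 1) stop("conf_level must be in (0, 1)")
  if (!is.null(clock_file) && !file.exists(clock_file))
    stop("clock file not found: ", clock_file)
  structure(
    list(covariates = covariates, table1_variables = table1_variables,
         marginal = marginal, clock_file = clock_file, scope = scope,
         normality_overrides = normality_overrides, df_method = df_method,
         conf_level = conf_level, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

.fe_row <- function(fe) {
  data.frame(beta = fe$beta, se = fe$se, ci_low = fe$ci_low,
             ci_high = fe$ci_high, p_value = fe$p_value,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: clock evaluation (DNAm age per observation),
#' residual regression and age acceleration, paired descriptive summary,
#' per-timepoint age correlations, change models (univariate and
#' covariate-adjusted), the interaction and adjusted covariate
#' batteries, and marginal means — then all result files are written to
#' `outdir`. Outputs are deterministic for fixed input and config
#' (reruns are byte-identical); warnings (singular fits, extrapolation)
#' are collected into the returned run log and re-emitted to the
#' console.
#'
#' @param data Validated long cohort data frame (see
#'   [read_cohort_csv()]).
#' @param config A [pipeline_config()].
#' @param outdir Output directory, created if needed.
#' @return Object of class `run_log`: per-stage records (stage, status,
#'   timestamp, notes), the config, and the paths written. The computed
#'   results are attached as attribute `"results"`.
#' @export
run_pipeline <- function(data, config = pipeline_config(), outdir) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  validate_cohort(data)
  unknown <- setdiff(c(config$covariates, names(config$marginal)), names(data))
  if (length(unknown) > 0)
    stop("config references unknown covariate(s): ",
         paste(unique(unknown), collapse = ", "))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  clock <- if (is.null(config$clock_file)) default_clock() else read_clock(config$clock_file)

  log_records <- list()
  warn_notes <- character()
  stage <- function(name, expr) {
    res <- withCallingHandlers(expr, warning = function(w) {
      warn_notes <<- c(warn_notes, paste0(name, ": ", conditionMessage(w)))
      message("[", name, "] warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    log_records[[length(log_records) + 1]] <<- data.frame(
      stage = name, status = "ok", timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      stringsAsFactors = FALSE)
    res
  }

  data <- stage("clock", {
    data$dnam_age <- batch_dnam_age(data, clock)
    data
  })
  data <- stage("acceleration", {
    fit <- fit_age_regression(data, config$scope)
    compute_age_acceleration(data, fit)
  })
  table1 <- stage("descriptives", {
    vars <- config$table1_variables
    if (is.null(vars))
      vars <- intersect(c("age", "dnam_age", "age_accel", "sex", config$covariates),
                        names(data))
    summarize_cohort(data, vars, overrides = config$normality_overrides)
  })
  correlations <- stage("correlations", age_correlations(data))
  battery <- stage("mixed_models", analyze_cohort(data, config))

  results <- c(list(data = data, table1 = table1, correlations = correlations),
               battery)
  paths <- stage("write", write_results(results, outdir))

  log <- structure(
    list(records = do.call(rbind, log_records), config = config,
         warnings = warn_notes, paths = paths),
    class = "run_log"
  )
  attr(log, "results") <- results
  invisible(log)
}

#' Run the mixed-model battery on a cohort with age acceleration
#'
#' Fits the change models (univariate plus one adjusted model per
#' marginal-means covariate), the per-covariate interaction and adjusted
#' models, and the marginal means, returning flat result tables.
#'
#' @param data Long cohort data frame with `age_accel` (see
#'   [compute_age_acceleration()]).
#' @param config A [pipeline_config()].
#' @return Named list of data frames: `change` (one contrast row per
#'   model), `interaction` (per covariate, effect at T0 and T6 plus
#'   interaction p), `adjusted` (per covariate, treatment-adjusted
#'   effect), `marginal` (per covariate, per-timepoint means at the
#'   fixed value). Tables for an empty covariate list have headers only.
#' @export
analyze_cohort <- function(data, config = pipeline_config()) {
  if (!"age_accel" %in% names(data))
    stop("data must contain 'age_accel'; run compute_age_acceleration first")
  empty_fe <- data.frame(beta = numeric(0), se = numeric(0),
                         ci_low = numeric(0), ci_high = numeric(0),
                         p_value = numeric(0))
  uni <- fit_change_model(data, NULL, config$df_method, config$conf_level)
  change <- cbind(data.frame(model = "univariate", term = "T6 - T0"),
                  .fe_row(uni$contrast))
  for (cv in names(config$marginal)) {
    adj <- fit_change_model(data, cv, config$df_method, config$conf_level)
    change <- rbind(change,
                    cbind(data.frame(model = paste0("adjusted_", cv),
                                     term = "T6 - T0"),
                          .fe_row(adj$contrast)))
  }
  interaction_tab <- if (length(config$covariates) == 0) {
    cbind(data.frame(covariate = character(0), effect = character(0)),
          empty_fe, data.frame(interaction_p = numeric(0)))
  } else {
    do.call(rbind, lapply(config$covariates, function(cv) {
      m <- fit_interaction_model(data, cv, config$df_method, config$conf_level)
      rbind(
        cbind(data.frame(covariate = cv, effect = "effect at T0"),
              .fe_row(m$effect_at_t0),
              data.frame(interaction_p = m$interaction_p)),
        cbind(data.frame(covariate = cv, effect = "effect at T6"),
              .fe_row(m$effect_at_t6),
              data.frame(interaction_p = m$interaction_p))
      )
    }))
  }
  adjusted_tab <- if (length(config$covariates) == 0) {
    cbind(data.frame(covariate = character(0)), empty_fe)
  } else {
    do.call(rbind, lapply(config$covariates, function(cv) {
      m <- fit_adjusted_model(data, cv, config$df_method, config$conf_level)
      cbind(data.frame(covariate = cv), .fe_row(m$covariate_effect))
    }))
  }
  marginal_tab <- if (length(config$marginal) == 0) NULL else {
    do.call(rbind, lapply(names(config$marginal), function(cv) {
      mm <- marginal_means(data, cv, config$marginal[[cv]],
                           config$df_method, config$conf_level)
      cbind(data.frame(covariate = cv, fixed_value = mm$fixed_value),
            mm$means, data.frame(comparison_p = mm$comparison_p))
    }))
  }
  list(change = change, interaction = interaction_tab,
       adjusted = adjusted_tab, marginal = marginal_tab)
}

#' Write pipeline result files
#'
#' Writes CSVs mirroring the paired-summary, per-timepoint correlation,
#' change-contrast, interaction (per-covariate effect at T0/T6 plus
#' interaction p), adjusted-association and marginal-means layouts.
#' Numeric columns keep full precision (at least 6 significant digits).
#' Files contain no timestamps, so identical inputs produce
#' byte-identical outputs.
#'
#' @param results Named list as assembled by [run_pipeline()]; elements
#'   that are `NULL` are skipped, but empty data frames still produce
#'   header-only files.
#' @param outdir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_results <- function(results, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- c(data = "accel.csv", table1 = "table1.csv",
             correlations = "age_correlations.csv",
             change = "change_contrasts.csv",
             interaction = "interaction_effects.csv",
             adjusted = "adjusted_effects.csv",
             marginal = "marginal_means.csv")
  paths <- character(0)
  for (nm in names(files)) {
    obj <- results[[nm]]
    if (is.null(obj)) next
    path <- file.path(outdir, files[[nm]])
    utils::write.csv(obj, path, row.names = FALSE)
    paths[nm] <- path
  }
  invisible(paths)
}

#' @export
print.run_log <- function(x, ...) {
  cat("<run_log>\n")
  print(x$records, row.names = FALSE)
  if (length(x$warnings) > 0) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}
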