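# Epigenetic age acceleration: residuals of DNAm age on chronological age.

#' Fit the DNAm-age-on-chronological-age regression
#'
#' Ordinary least squares of `dnam_age` on `age` over the scoped
#' observations. Age acceleration is later computed as the residual from
#' this line, so accelerations over the fitting scope sum to zero and are
#' uncorrelated with chronological age by construction.
#'
#' The default scope pools both timepoints into one regression. With
#' complete pairs this makes the T0 and T6 mean accelerations exactly
#' equal in magnitude and opposite in sign; `baseline_only` restricts the
#' fit to T0 rows and is kept for scoring follow-up data against a
#' baseline-frozen line.
#'
#' @param data Long-format cohort data frame with columns `age` (years,
#'   chronological) and `dnam_age` (years), plus `timepoint` when
#'   `scope = "baseline_only"`.
#' @param scope `"pooled"` (default) or `"baseline_only"`.
#' @return An object of class `age_regression`: list with `intercept`,
#'   `slope`, `n_obs`, `scope`.
#' @export
fit_age_regression <- function(data, scope = c("pooled", "baseline_only")) {
  scope <- match.arg(scope)
  if (!all(c("age", "dnam_age") %in% names(data)))
    stop("data must contain 'age' and 'dnam_age' columns")
  sub <- if (scope == "baseline_only") {
    if (!"timepoint" %in% names(data))
      stop("baseline_only scope requires a 'timepoint' column")
    data[data$timepoint == "T0", , drop = FALSE]
  } else data
  if (nrow(sub) < 3) stop("need at least 3 observations to fit, got ", nrow(sub))
  if (anyNA(sub$age) || anyNA(sub$dnam_age))
    stop("age and dnam_age must be complete (no NA) within the fitting scope")
  if (stats::var(sub$age) == 0)
    stop("chronological age has zero variance in the fitting scope; singular fit")
  fit <- stats::lm(dnam_age ~ age, data = sub)
  structure(
    list(
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      n_obs = nrow(sub),
      scope = scope
    ),
    class = "age_regression"
  )
}

#' @export
print.age_regression <- function(x, ...) {
  cat(sprintf(
    "<age_regression> dnam_age = %.4f + %.4f x age  (n = %d, scope = %s)\n",
    x$intercept, x$slope, x$n_obs, x$scope))
  invisible(x)
}

#' Compute per-observation age acceleration
#'
#' Age acceleration is the residual of DNAm age from the fitted regression
#' line: `dnam_age - (intercept + slope * age)`. Positive values mean the
#' subject looks biologically older than expected for their chronological
#' age. Residuals are computed against the fit's stored coefficients (not
#' refit), so new observations can be scored against a frozen line.
#'
#' @param data Cohort data frame with `age` and `dnam_age` columns.
#' @param fit An `age_regression` object, typically from
#'   [fit_age_regression()] on the same data.
#' @return `data` with an `age_accel` column appended (years).
#' @export
compute_age_acceleration <- function(data, fit) {
  if (!inherits(fit, "age_regression")) stop("fit must be an age_regression")
  if (!all(c("age", "dnam_age") %in% names(data)))
    stop("data must contain 'age' and 'dnam_age' columns")
  if (anyNA(data$dnam_age)) {
    bad <- which(is.na(data$dnam_age))[1]
    stop("dnam_age is missing at row ", bad)
  }
  data$age_accel <- data$dnam_age - (fit$intercept + fit$slope * data$age)
  data
}
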