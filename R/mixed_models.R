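# Longitudinal inference battery: random-intercept models for paired data.
#
# All models share the structure
#   age_accel ~ time [+ covariate [+ time:covariate]] + (1 | subject)
# fitted by REML, with time coded 0/1 (T0 reference) so the time
# coefficient is the printed "T6 - T0" difference. Wald t tests and CIs
# use residual (between-within) degrees of freedom by default;
# Satterthwaite is available via `df_method`.

.check_long_pairs <- function(data) {
  need <- c("subject_id", "timepoint")
  if (!all(need %in% names(data)))
    stop("data must contain columns: ", paste(need, collapse = ", "))
  if (!all(data$timepoint %in% c("T0", "T6")))
    stop("timepoint values must be 'T0' or 'T6'")
  tab <- table(data$subject_id, data$timepoint)
  if (ncol(tab) < 2 || any(tab != 1)) {
    bad <- rownames(tab)[rowSums(tab == 1) != 2 | rowSums(tab) != 2]
    if (length(bad) == 0) bad <- "?"
    stop("each subject needs exactly one T0 and one T6 row; offending subject(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

.mm_prepare <- function(data, covariate = NULL) {
  .check_long_pairs(data)
  if (!"age_accel" %in% names(data))
    stop("data must contain an 'age_accel' column (see compute_age_acceleration)")
  df <- data.frame(
    age_accel = data$age_accel,
    time = as.integer(data$timepoint == "T6"),
    subject_id = factor(data$subject_id),
    stringsAsFactors = FALSE
  )
  if (!is.null(covariate)) {
    if (!covariate %in% names(data)) stop("unknown covariate: ", covariate)
    df$covariate <- data[[covariate]]
    if (anyNA(df$covariate)) stop("covariate '", covariate, "' has missing values")
    if (stats::var(df$covariate) == 0)
      stop("covariate '", covariate, "' is constant; singular design")
  }
  if (anyNA(df$age_accel)) stop("age_accel has missing values")
  df
}

# REML random-intercept fit; returns fixed effects, their covariance,
# df per method, and a singular-variance flag.
.mm_fit <- function(df, rhs, df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), df)
  if (qr(X)$rank < ncol(X))
    stop("singular design: fixed-effects matrix is rank-deficient")
  form <- stats::as.formula(paste("age_accel ~", rhs, "+ (1 | subject_id)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE)
  if (df_method == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE))
      stop("df_method = 'satterthwaite' requires the lmerTest package")
    fit <- suppressMessages(
      lmerTest::lmer(form, data = df, REML = TRUE, control = ctrl))
    dfs <- stats::coef(summary(fit))[, "df"]
  } else {
    fit <- suppressMessages(
      lme4::lmer(form, data = df, REML = TRUE, control = ctrl))
    dfs <- rep(nrow(df) - ncol(X), ncol(X))
  }
  beta <- lme4::fixef(fit)
  # a perfectly deterministic response collapses the residual variance to
  # zero and the covariance computation with it; report zero SEs then
  V <- tryCatch(as.matrix(stats::vcov(fit)), error = function(e) {
    matrix(0, length(beta), length(beta),
           dimnames = list(names(beta), names(beta)))
  })
  list(
    fit = fit,
    beta = beta,
    vcov = V,
    dfs = dfs,
    n_obs = nrow(df),
    df_method = df_method,
    singular = lme4::isSingular(fit)
  )
}

.fixed_effect <- function(term, beta, se, df, conf_level = 0.95) {
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  tval <- beta / se
  data.frame(
    term = term, beta = beta, se = se,
    ci_low = beta - tcrit * se, ci_high = beta + tcrit * se,
    df = df, p_value = 2 * stats::pt(-abs(tval), df),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.fe_table <- function(m, conf_level) {
  terms <- names(m$beta)
  do.call(rbind, lapply(seq_along(terms), function(i) {
    .fixed_effect(terms[i], unname(m$beta[i]), sqrt(m$vcov[i, i]),
                  m$dfs[i], conf_level)
  }))
}

# SE/df for a linear combination L'beta
.combo_effect <- function(m, L, term, conf_level) {
  beta <- sum(L * m$beta)
  se <- sqrt(drop(t(L) %*% m$vcov %*% L))
  df <- if (m$df_method == "satterthwaite") {
    ct <- lmerTest::contest1D(m$fit, L, confint = FALSE)
    ct$df
  } else m$n_obs - length(m$beta)
  .fixed_effect(term, beta, se, df, conf_level)
}

#' Treatment-contrast (change) model for age acceleration
#'
#' Fits `age_accel ~ time [+ covariate] + (1 | subject)` by REML and
#' returns the T6 - T0 contrast: the coefficient of the time indicator.
#' On complete pairs the univariate contrast equals the paired mean
#' difference of the response. Adding a covariate (e.g. IGF-1) gives the
#' covariate-adjusted treatment contrast.
#'
#' @param data Long cohort data frame with `subject_id`, `timepoint`
#'   (`"T0"`/`"T6"`, complete pairs), `age_accel`, and the covariate
#'   column when requested.
#' @param covariate Optional covariate column name.
#' @param df_method `"residual"` (observations minus fixed-effect
#'   parameters; default) or `"satterthwaite"` (via lmerTest).
#' @param conf_level Confidence level for CIs.
#' @return Object of class `change_model`: `contrast` (one-row fixed-effect
#'   data frame for T6 - T0), `covariate_effect` (or `NULL`), `effects`
#'   (full fixed-effects table), `covariate`, `singular`, `model`.
#' @export
fit_change_model <- function(data, covariate = NULL,
                             df_method = c("residual", "satterthwaite"),
                             conf_level = 0.95) {
  df_method <- match.arg(df_method)
  df <- .mm_prepare(data, covariate)
  rhs <- if (is.null(covariate)) "time" else "time + covariate"
  m <- .mm_fit(df, rhs, df_method)
  tab <- .fe_table(m, conf_level)
  contrast <- tab[tab$term == "time", , drop = FALSE]
  contrast$term <- "T6 - T0"
  cov_eff <- NULL
  if (!is.null(covariate)) {
    cov_eff <- tab[tab$term == "covariate", , drop = FALSE]
    cov_eff$term <- covariate
  }
  structure(
    list(contrast = contrast, covariate_effect = cov_eff, effects = tab,
         covariate = covariate, conf_level = conf_level,
         df_method = df_method, singular = m$singular, model = m),
    class = "change_model"
  )
}

#' @export
print.change_model <- function(x, ...) {
  cat("<change_model>",
      if (is.null(x$covariate)) "univariate"
      else paste0("adjusted for ", x$covariate), "\n")
  print(x$contrast, row.names = FALSE)
  if (x$singular) cat("  note: singular random-effect variance\n")
  invisible(x)
}

#' Effect-modification (interaction) model
#'
#' Fits `age_accel ~ time * covariate + (1 | subject)` by REML and
#' reports the covariate effect separately per timepoint: the effect at
#' T0 is the covariate main effect; the effect at T6 is the main effect
#' plus the interaction coefficient, with its standard error from the
#' covariance of that linear combination. The interaction p-value tests
#' whether treatment modifies the covariate association.
#'
#' @inheritParams fit_change_model
#' @param covariate Covariate column name (required).
#' @return Object of class `interaction_model`: `effect_at_t0`,
#'   `effect_at_t6` (one-row fixed-effect data frames), `interaction_p`,
#'   `effects`, `singular`, `model`.
#' @export
fit_interaction_model <- function(data, covariate,
                                  df_method = c("residual", "satterthwaite"),
                                  conf_level = 0.95) {
  df_method <- match.arg(df_method)
  if (missing(covariate) || is.null(covariate))
    stop("fit_interaction_model requires a covariate")
  df <- .mm_prepare(data, covariate)
  m <- .mm_fit(df, "time * covariate", df_method)
  tab <- .fe_table(m, conf_level)
  i_cov <- which(names(m$beta) == "covariate")
  i_int <- which(names(m$beta) == "time:covariate")
  eff_t0 <- tab[i_cov, , drop = FALSE]
  eff_t0$term <- paste0(covariate, " (effect at T0)")
  L <- as.numeric(names(m$beta) %in% c("covariate", "time:covariate"))
  eff_t6 <- .combo_effect(m, L, paste0(covariate, " (effect at T6)"), conf_level)
  structure(
    list(effect_at_t0 = eff_t0, effect_at_t6 = eff_t6,
         interaction_p = tab$p_value[i_int], effects = tab,
         covariate = covariate, conf_level = conf_level,
         df_method = df_method, singular = m$singular, model = m),
    class = "interaction_model"
  )
}

#' @export
print.interaction_model <- function(x, ...) {
  cat("<interaction_model> covariate:", x$covariate, "\n")
  print(rbind(x$effect_at_t0, x$effect_at_t6), row.names = FALSE)
  cat(sprintf("  interaction p = %.4g\n", x$interaction_p))
  invisible(x)
}

#' Treatment-adjusted covariate association
#'
#' Fits `age_accel ~ time + covariate + (1 | subject)` by REML and
#' returns the covariate effect adjusted for treatment (time). The beta
#' is per raw covariate unit (covariates enter untransformed and
#' uncentered).
#'
#' @inheritParams fit_interaction_model
#' @return Object of class `adjusted_model`: `covariate_effect` (one-row
#'   fixed-effect data frame), `effects`, `singular`, `model`.
#' @export
fit_adjusted_model <- function(data, covariate,
                               df_method = c("residual", "satterthwaite"),
                               conf_level = 0.95) {
  if (missing(covariate) || is.null(covariate))
    stop("fit_adjusted_model requires a covariate")
  cm <- fit_change_model(data, covariate, df_method, conf_level)
  structure(
    list(covariate_effect = cm$covariate_effect, effects = cm$effects,
         covariate = covariate, conf_level = cm$conf_level,
         df_method = cm$df_method, singular = cm$singular, model = cm$model),
    class = "adjusted_model"
  )
}

#' @export
print.adjusted_model <- function(x, ...) {
  cat("<adjusted_model> covariate:", x$covariate, "(adjusted for treatment)\n")
  print(x$covariate_effect, row.names = FALSE)
  invisible(x)
}

#' Marginal means of age acceleration at a fixed covariate value
#'
#' From the covariate-adjusted change model, computes the model-predicted
#' mean age acceleration per timepoint with the covariate held at
#' `fixed_value` (e.g. IGF-1 at its baseline median), with CIs from the
#' fixed-effects covariance. The difference of the two means equals the
#' adjusted T6 - T0 contrast, and the comparison p-value is the
#' contrast's p-value.
#'
#' @param data Long cohort data frame (see [fit_change_model()]).
#' @param covariate Covariate column name.
#' @param fixed_value Covariate value at which means are evaluated; a
#'   value outside the observed covariate range triggers an extrapolation
#'   warning, not an error.
#' @inheritParams fit_change_model
#' @return Object of class `marginal_means`: `means` (data frame with
#'   `timepoint`, `mean`, `se`, `ci_low`, `ci_high`), `comparison_p`,
#'   `contrast`, `covariate`, `fixed_value`.
#' @export
marginal_means <- function(data, covariate, fixed_value,
                           df_method = c("residual", "satterthwaite"),
                           conf_level = 0.95) {
  df_method <- match.arg(df_method)
  cm <- fit_change_model(data, covariate, df_method, conf_level)
  obs <- data[[covariate]]
  if (fixed_value < min(obs) || fixed_value > max(obs))
    warning("fixed_value ", fixed_value, " lies outside the observed range of '",
            covariate, "' [", min(obs), ", ", max(obs), "]; extrapolating")
  m <- cm$model
  rows <- lapply(c(T0 = 0, T6 = 1), function(t01) {
    L <- c(1, t01, fixed_value)  # (Intercept), time, covariate
    .combo_effect(m, L, if (t01 == 0) "T0" else "T6", conf_level)
  })
  means <- do.call(rbind, rows)
  means <- data.frame(timepoint = means$term, mean = means$beta, se = means$se,
                      ci_low = means$ci_low, ci_high = means$ci_high,
                      stringsAsFactors = FALSE)
  structure(
    list(means = means, comparison_p = cm$contrast$p_value,
         contrast = cm$contrast, covariate = covariate,
         fixed_value = fixed_value, conf_level = conf_level),
    class = "marginal_means"
  )
}

#' @export
print.marginal_means <- function(x, ...) {
  cat(sprintf("<marginal_means> %s fixed at %g\n", x$covariate, x$fixed_value))
  print(x$means, row.names = FALSE)
  cat(sprintf("  T6 vs T0 comparison p = %.4g\n", x$comparison_p))
  invisible(x)
}
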