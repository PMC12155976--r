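# Paired pre/post descriptive statistics: paired t, exact Wilcoxon
# signed-rank, Spearman correlation, HOMA-IR, Table-1-style summaries.

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' `insulin (uIU/mL) x glucose (mmol/L) / 22.5`, with glucose supplied in
#' mg/dL and converted by dividing by 18.016 (the molar mass of glucose in
#' mg/mmol per dL-to-L scaling).
#'
#' @param insulin Fasting insulin, uIU/mL (= mU/L). Must be positive.
#' @param glucose Fasting glucose, mg/dL. Must be positive.
#' @return HOMA-IR index (unitless); vectorized.
#' @examples
#' homa_ir(22.5, 18.016)  # 1 by construction
#' @export
homa_ir <- function(insulin, glucose) {
  if (any(!is.finite(insulin)) || any(!is.finite(glucose)))
    stop("insulin and glucose must be finite")
  if (any(insulin <= 0) || any(glucose <= 0))
    stop("insulin and glucose must be positive")
  insulin * (glucose / 18.016) / 22.5
}

#' Paired t-test for a pre/post variable
#'
#' Two-sided paired t-test of the T6 - T0 differences.
#'
#' @param x_t0,x_t6 Paired numeric vectors (same subjects, same order).
#' @return A `paired_comparison` list: `test_used`, `estimate` (mean of
#'   T6 - T0), `statistic`, `df`, `p_value`, `n`.
#' @export
paired_t_test <- function(x_t0, x_t6) {
  .check_pairs(x_t0, x_t6)
  d <- x_t6 - x_t0
  if (stats::sd(d) == 0)
    stop("all paired differences are identical; paired t-test is degenerate")
  ht <- stats::t.test(x_t6, x_t0, paired = TRUE)
  structure(
    list(
      test_used = "paired_t",
      estimate = unname(ht$estimate),
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = ht$p.value,
      n = length(d)
    ),
    class = "paired_comparison"
  )
}

.check_pairs <- function(x_t0, x_t6) {
  if (length(x_t0) != length(x_t6))
    stop("x_t0 and x_t6 must have equal length")
  if (length(x_t0) < 2) stop("need at least 2 pairs")
  if (anyNA(x_t0) || anyNA(x_t6)) stop("missing values in paired vectors")
  invisible(TRUE)
}

# Exact two-sided p for the signed-rank statistic W (sum of ranks of
# positive differences, mid-ranks for ties) by convolution over all 2^n
# sign assignments. Ranks are doubled so tied mid-ranks (halves) become
# integers; the distribution is built with the shift algorithm.
.signrank_exact_p <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # f[k+1] = number of sign assignments with doubled statistic k
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in r2) {
    g <- numeric(total + 1)
    g[1:(total + 1 - r)] <- f[1:(total + 1 - r)]
    f <- f + c(numeric(r), g[1:(total + 1 - r)])
  }
  probs <- f / 2^length(ranks)
  w2 <- round(2 * w)
  lower <- sum(probs[seq_len(w2 + 1)])           # P(W <= w)
  upper <- sum(probs[seq(w2 + 1, total + 1)])    # P(W >= w)
  min(1, 2 * min(lower, upper))
}

#' Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped before ranking; ties receive mid-ranks.
#' The statistic `W` is the sum of ranks of positive differences. In
#' `exact` mode (the default for small samples) the two-sided p-value is
#' computed from the full distribution of W over all `2^n` sign
#' assignments, which remains valid under ties; `approximate` mode uses
#' the normal approximation with tie correction.
#'
#' @param x_t0,x_t6 Paired numeric vectors.
#' @param mode `"exact"` (requires at most 25 nonzero differences) or
#'   `"approximate"`.
#' @return A `paired_comparison` list with `test_used = "wilcoxon_signed_rank"`,
#'   `statistic` (W), `p_value`, `n` (nonzero differences), `mode`.
#' @export
wilcoxon_signed_rank <- function(x_t0, x_t6, mode = c("exact", "approximate")) {
  mode <- match.arg(mode)
  .check_pairs(x_t0, x_t6)
  d <- x_t6 - x_t0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero; test is degenerate")
  if (mode == "exact" && n > 25)
    stop("exact mode supports at most 25 nonzero differences, got ", n)
  ranks <- rank(abs(d))
  w <- sum(ranks[d > 0])
  if (mode == "exact") {
    p <- .signrank_exact_p(w, ranks)
  } else {
    ew <- n * (n + 1) / 4
    tie_tab <- table(ranks)
    vw <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w - ew) / sqrt(vw)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(
      test_used = "wilcoxon_signed_rank",
      estimate = stats::median(d),
      statistic = w,
      p_value = p,
      n = n,
      mode = mode
    ),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s: statistic = %.4g, p = %.4g (n = %d)\n",
              x$test_used, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Mid-ranks for ties; rho is the Pearson correlation of the ranks. The
#' p-value is exact (full permutation distribution) when `n <= 10` and
#' there are no ties, otherwise the t approximation on `n - 2` degrees of
#' freedom is used.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return List of class `correlation_result`: `rho`, `p_value`, `n`,
#'   `method` (`"exact"` or `"t_approx"`).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  has_ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (!has_ties && n <= 10) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    if (abs(rho) == 1) p <- 0
    method <- "t_approx"
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho = %.4f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

#' Spearman correlation of chronological and DNAm age per timepoint
#'
#' @param data Cohort data frame with `timepoint`, `age`, `dnam_age`.
#' @return Data frame with one row per timepoint: `timepoint`, `rho`,
#'   `p_value`, `n`.
#' @export
age_correlations <- function(data) {
  if (!all(c("timepoint", "age", "dnam_age") %in% names(data)))
    stop("data must contain 'timepoint', 'age', 'dnam_age'")
  tps <- sort(unique(data$timepoint))
  rows <- lapply(tps, function(tp) {
    sub <- data[data$timepoint == tp, ]
    r <- spearman_cor(sub$age, sub$dnam_age)
    data.frame(timepoint = tp, rho = r$rho, p_value = r$p_value, n = r$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.fmt_mean_sd <- function(x) sprintf("%.4g ± %.3g", mean(x), stats::sd(x))
.fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  sprintf("%.4g [%.4g;%.4g]", q[2], q[1], q[3])
}

#' Paired cohort summary table
#'
#' Builds a baseline-vs-follow-up comparison table. Each numeric variable
#' is routed by a normality policy: Shapiro-Wilk on its pooled values at
#' `alpha = 0.05` selects the paired t-test (summarized mean +/- SD) when
#' normality is not rejected, and the exact Wilcoxon signed-rank test
#' (summarized median \[Q1;Q3\], type-7 quartiles) otherwise. Per-variable
#' overrides can force either route. Non-numeric variables are reported as
#' frequencies with no test.
#'
#' @param data Long cohort data frame with `subject_id` and `timepoint`
#'   (values `"T0"`, `"T6"`), complete pairs.
#' @param variables Character vector of column names to summarize.
#' @param overrides Optional named character vector mapping variable names
#'   to `"paired_t"` or `"wilcoxon"`, bypassing the normality policy.
#' @param alpha Shapiro-Wilk significance level for the policy.
#' @return Data frame: `variable`, `summary_t0`, `summary_t6`,
#'   `test_used`, `statistic`, `p_value`.
#' @export
summarize_cohort <- function(data, variables, overrides = NULL, alpha = 0.05) {
  .check_long_pairs(data)
  t0 <- data[data$timepoint == "T0", ]
  t0 <- t0[order(t0$subject_id), ]
  t6 <- data[data$timepoint == "T6", ]
  t6 <- t6[order(t6$subject_id), ]
  rows <- lapply(variables, function(v) {
    if (!v %in% names(data)) stop("unknown variable: ", v)
    x0 <- t0[[v]]; x6 <- t6[[v]]
    if (!is.numeric(x0)) {
      tab <- table(c(as.character(x0), as.character(x6)))
      lab <- paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = "; ")
      return(data.frame(variable = v, summary_t0 = lab, summary_t6 = lab,
                        test_used = "none", statistic = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    route <- if (!is.null(overrides) && v %in% names(overrides)) {
      match.arg(overrides[[v]], c("paired_t", "wilcoxon"))
    } else {
      sw <- stats::shapiro.test(c(x0, x6))
      if (sw$p.value >= alpha) "paired_t" else "wilcoxon"
    }
    # degenerate pairings (all differences equal / all zero) are reported
    # with NA statistics instead of aborting the whole table
    res <- tryCatch(
      if (route == "paired_t") paired_t_test(x0, x6)
      else wilcoxon_signed_rank(x0, x6, mode = if (sum(x6 != x0) <= 25) "exact" else "approximate"),
      error = function(e) list(test_used = route, statistic = NA_real_,
                               p_value = NA_real_)
    )
    fmt <- if (route == "paired_t") .fmt_mean_sd else .fmt_median_iqr
    data.frame(variable = v, summary_t0 = fmt(x0), summary_t6 = fmt(x6),
               test_used = res$test_used, statistic = res$statistic,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
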