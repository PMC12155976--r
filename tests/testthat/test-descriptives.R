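# Paired descriptive statistics and derived indices.

test_that("HOMA-IR follows the insulin x glucose(mmol/L) / 22.5 construction", {
  expect_equal(homa_ir(22.5, 18.016), 1, tolerance = 1e-12)
  # frozen from an independent single-line arithmetic check
  expect_equal(homa_ir(10, 90), 2.2202486678507993, tolerance = 1e-12)
  expect_lt(homa_ir(1e-4, 90), 1e-4)
  expect_error(homa_ir(0, 90), "positive")
  expect_error(homa_ir(10, -1), "positive")
})

test_that("paired t-test matches the textbook formula", {
  set.seed(21)
  x0 <- rnorm(10, 10, 2)
  x6 <- x0 + rnorm(10, 1, 1.5)
  res <- paired_t_test(x0, x6)
  d <- x6 - x0
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * pt(-abs(t_oracle), df = length(d) - 1)
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_identical(res$df, 9)
})

test_that("paired t-test recovers a pure location shift exactly", {
  x <- rnorm(8)
  res <- paired_t_test(x, x + 2.5 + rnorm(8, 0, 1e-8))
  expect_equal(res$estimate, 2.5, tolerance = 1e-6)
  expect_error(paired_t_test(x, x + 3), "degenerate")
})

test_that("extreme orderings give the boundary exact Wilcoxon p", {
  # all eight differences positive: W is maximal, two-sided p = 2/2^8
  res <- wilcoxon_signed_rank(1:8, (1:8) + runif(8, 0.5, 1))
  expect_equal(res$statistic, 36)
  expect_equal(res$p_value, 2 / 256, tolerance = 1e-12)
  # symmetric +a/-a differences sit at the centre: p near 1
  d <- c(1, -1, 2, -2, 3, -3, 4, -4)
  res2 <- wilcoxon_signed_rank(rep(0, 8), d)
  expect_gt(res2$p_value, 0.8)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
})

test_that("exact Wilcoxon p equals brute-force sign enumeration", {
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n, 0.3, 1), sample(c(1, 3), 1))  # ties likely at 1 digit
    d <- d[d != 0]
    if (length(d) < 3) next
    res <- wilcoxon_signed_rank(rep(0, length(d)), d, mode = "exact")
    expect_equal(res$p_value, brute_signrank_p(d), tolerance = 1e-12)
  }
})

test_that("approximate Wilcoxon mode tracks the exact p for moderate n", {
  set.seed(41)
  d <- rnorm(15, 0.4, 1)
  pe <- wilcoxon_signed_rank(rep(0, 15), d, mode = "exact")$p_value
  pa <- wilcoxon_signed_rank(rep(0, 15), d, mode = "approximate")$p_value
  expect_lt(abs(pe - pa), 0.05)
  expect_error(wilcoxon_signed_rank(rep(0, 30), rnorm(30), mode = "exact"),
               "at most 25")
})

test_that("Spearman rho hits the monotone boundaries and mid-rank ties", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  # tie handling: rho must equal the Pearson correlation of mid-ranks
  xt <- c(1, 2, 2, 3, 4, 5, 6, 7, 8, 9)
  yt <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  expect_equal(spearman_cor(xt, yt)$rho, cor(rank(xt), rank(yt)),
               tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(51)
  x <- rnorm(12)
  y <- rnorm(12)
  r0 <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x), y)$rho, r0, tolerance = 1e-12)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rho, r0, tolerance = 1e-12)
})

test_that("exact Spearman p equals brute-force permutation enumeration", {
  set.seed(61)
  for (n in c(5, 6, 7)) {
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    res <- spearman_cor(x, y)
    expect_identical(res$method, "exact")
    expect_equal(res$p_value, brute_spearman_p(x, y), tolerance = 1e-10)
  }
})

test_that("cohort summary routes variables by the normality policy", {
  set.seed(71)
  n <- 12
  extra <- data.frame(
    gaussian = rnorm(2 * n, 50, 5),
    skewed = rlnorm(2 * n, 0, 1.2),
    sex = rep(rep(c("M", "F"), each = 2), n / 2)
  )
  d <- paired_cohort(rnorm(2 * n), n = n, extra = extra)
  tab <- summarize_cohort(d, c("gaussian", "skewed", "sex"))
  # independently recompute the Shapiro-Wilk routing decision
  expect_identical(
    tab$test_used[tab$variable == "gaussian"],
    if (shapiro.test(extra$gaussian)$p.value >= 0.05) "paired_t" else "wilcoxon_signed_rank")
  expect_identical(tab$test_used[tab$variable == "gaussian"], "paired_t")
  expect_identical(tab$test_used[tab$variable == "skewed"], "wilcoxon_signed_rank")
  expect_identical(tab$test_used[tab$variable == "sex"], "none")
  expect_true(is.na(tab$p_value[tab$variable == "sex"]))
  expect_match(tab$summary_t0[tab$variable == "gaussian"], "±")
  expect_match(tab$summary_t0[tab$variable == "skewed"], "\\[.*;.*\\]")
  # manual override forces the other route
  tab2 <- summarize_cohort(d, "gaussian", overrides = c(gaussian = "wilcoxon"))
  expect_identical(tab2$test_used, "wilcoxon_signed_rank")
})

test_that("per-timepoint age correlations are reported for both visits", {
  cohort <- generate_cohort(cohort_params(), seed = 17)$data
  cohort$dnam_age <- batch_dnam_age(cohort)
  tab <- age_correlations(cohort)
  expect_identical(tab$timepoint, c("T0", "T6"))
  expect_identical(tab$n, c(10L, 10L))
  expect_true(all(tab$rho >= -1 & tab$rho <= 1))
})
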