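# Random-intercept inference battery.

make_accel_cohort <- function(n = 20, shift = -1.5, slope = 0,
                              sigma_u = 1.5, sigma_e = 1, seed = 101) {
  set.seed(seed)
  u <- rnorm(n, 0, sigma_u)
  x <- cbind(rlnorm(n, log(120), 0.4), NA)
  x[, 2] <- x[, 1] * 2.8 * exp(rnorm(n, 0, 0.3))
  accel <- as.vector(rbind(u + slope * (x[, 1] - 120) + rnorm(n, 0, sigma_e),
                           u + shift + slope * (x[, 2] - 120) + rnorm(n, 0, sigma_e)))
  paired_cohort(accel, n = n, extra = data.frame(igf1 = as.vector(t(x))))
}

test_that("the univariate change contrast equals the paired mean difference", {
  d <- make_accel_cohort()
  cm <- fit_change_model(d)
  t0 <- d$age_accel[d$timepoint == "T0"]
  t6 <- d$age_accel[d$timepoint == "T6"]
  expect_equal(cm$contrast$beta, mean(t6 - t0), tolerance = 1e-6)
  expect_identical(cm$contrast$term, "T6 - T0")
  expect_true(cm$contrast$ci_low <= cm$contrast$beta &&
                cm$contrast$beta <= cm$contrast$ci_high)
})

test_that("a response identical across timepoints gives a zero contrast", {
  u <- rnorm(10)
  d <- paired_cohort(rep(u, each = 2), n = 10)
  cm <- fit_change_model(d)
  expect_equal(cm$contrast$beta, 0, tolerance = 1e-8)
})

test_that("effect at T6 is the covariate beta plus the interaction beta", {
  d <- make_accel_cohort(slope = 0.011, seed = 103)
  im <- fit_interaction_model(d, "igf1")
  beta <- im$model$beta
  expect_equal(im$effect_at_t0$beta, unname(beta["covariate"]), tolerance = 1e-12)
  expect_equal(im$effect_at_t6$beta,
               unname(beta["covariate"] + beta["time:covariate"]),
               tolerance = 1e-12)
  # the combination SE comes from the fixed-effect covariance
  V <- im$model$vcov
  i <- which(names(beta) == "covariate"); j <- which(names(beta) == "time:covariate")
  expect_equal(im$effect_at_t6$se,
               sqrt(V[i, i] + V[j, j] + 2 * V[i, j]), tolerance = 1e-12)
  expect_true(im$interaction_p >= 0 && im$interaction_p <= 1)
})

test_that("a null interaction leaves the two timepoint effects close", {
  d <- make_accel_cohort(n = 60, slope = 0.011, sigma_e = 0.05, sigma_u = 0.5,
                         seed = 107)
  im <- fit_interaction_model(d, "igf1")
  expect_lt(abs(im$effect_at_t0$beta - 0.011), 5e-3)
  expect_lt(abs(im$effect_at_t6$beta - 0.011), 5e-3)
  expect_lt(abs(im$effect_at_t0$beta - im$effect_at_t6$beta), 5e-3)
})

test_that("a noiseless proportional response recovers its slope exactly", {
  set.seed(109)
  x <- as.vector(rbind(runif(10, 0, 10), runif(10, 0, 10)))
  d <- paired_cohort(2 * x, n = 10, extra = data.frame(cov = x))
  # zero residual variance: the point estimate is exact, the vcov is not
  m <- suppressWarnings(fit_adjusted_model(d, "cov"))
  expect_equal(m$covariate_effect$beta, 2, tolerance = 1e-6)
})

test_that("constant covariates raise a singular-design error", {
  d <- make_accel_cohort()
  d$flat <- 3.2
  expect_error(fit_adjusted_model(d, "flat"), "constant|singular")
  expect_error(fit_interaction_model(d, "flat"), "constant|singular")
})

test_that("marginal means are affine in the fixed covariate value", {
  d <- make_accel_cohort(slope = 0.011, seed = 113)
  suppressWarnings({
    mm1 <- marginal_means(d, "igf1", 120)
    mm2 <- marginal_means(d, "igf1", 200)
  })
  cm <- fit_change_model(d, "igf1")
  bcov <- cm$covariate_effect$beta
  expect_equal(mm2$means$mean - mm1$means$mean, rep(bcov * 80, 2),
               tolerance = 1e-9)
  # the T6 - T0 difference of means is exactly the adjusted contrast
  expect_equal(diff(mm1$means$mean), cm$contrast$beta, tolerance = 1e-9)
  expect_equal(mm1$comparison_p, cm$contrast$p_value, tolerance = 1e-12)
})

test_that("marginal means agree with an independent emmeans computation", {
  skip_if_not_installed("emmeans")
  skip_if_not_installed("lmerTest")
  d <- make_accel_cohort(slope = 0.011, seed = 127)
  mm <- marginal_means(d, "igf1", 150)
  df <- data.frame(age_accel = d$age_accel,
                   time = as.integer(d$timepoint == "T6"),
                   igf1 = d$igf1, subject_id = factor(d$subject_id))
  fit <- lme4::lmer(age_accel ~ time + igf1 + (1 | subject_id), data = df,
                    REML = TRUE)
  em <- as.data.frame(emmeans::emmeans(fit, ~ time, at = list(time = c(0, 1),
                                                              igf1 = 150),
                                       lmer.df = "asymptotic"))
  expect_equal(mm$means$mean, em$emmean, tolerance = 1e-6)
})

test_that("marginal means warn on extrapolation beyond the covariate range", {
  d <- make_accel_cohort(seed = 131)
  expect_warning(marginal_means(d, "igf1", 1e5), "outside")
})

test_that("Satterthwaite df can be swapped in without changing the estimates", {
  skip_if_not_installed("lmerTest")
  d <- make_accel_cohort(seed = 139)
  cm_r <- fit_change_model(d, "igf1", df_method = "residual")
  cm_s <- fit_change_model(d, "igf1", df_method = "satterthwaite")
  expect_false(cm_r$singular)  # a boundary fit would collapse the df anyway
  expect_equal(cm_s$contrast$beta, cm_r$contrast$beta, tolerance = 1e-6)
  expect_equal(cm_s$contrast$se, cm_r$contrast$se, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(cm_s$contrast$df, cm_r$contrast$df)))
})

test_that("incomplete pairs are rejected", {
  d <- make_accel_cohort()
  expect_error(fit_change_model(d[-2, ]), "S01")
})
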