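# Synthetic cohort generator and ground-truth recovery.

test_that("generation is deterministic for a fixed seed", {
  a <- generate_cohort(cohort_params(), seed = 17)
  b <- generate_cohort(cohort_params(), seed = 17)
  expect_identical(a$data, b$data)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_params(), seed = 18)
  expect_false(identical(a$data, c$data))
})

test_that("generated cohorts satisfy the paired-dataset invariants", {
  co <- generate_cohort(cohort_params(n_subjects = 25), seed = 23)
  expect_silent(validate_cohort(co$data))
  tab <- table(co$data$subject_id, co$data$timepoint)
  expect_true(all(tab == 1))
  meth <- as.matrix(co$data[, clock_genes])
  expect_true(all(meth >= 0 & meth <= 100))
})

test_that("the clock reproduces every intended DNAm age", {
  co <- generate_cohort(cohort_params(n_subjects = 40), seed = 29)
  expect_equal(batch_dnam_age(co$data), co$truth$target_dnam_age,
               tolerance = 1e-9)
})

test_that("clock inversion is a fixed point at the current age and round-trips", {
  clock <- default_clock()
  set.seed(37)
  ref <- random_profile()
  cur <- compute_dnam_age(ref, clock)
  expect_equal(invert_clock(cur, ref, clock), ref, tolerance = 1e-12)
  # a low-age reference leaves headroom for targets across childhood
  ref2 <- stats::setNames(c(15, 86.6, 15, 12, 25), clock_genes)
  for (target in runif(100, 2, 30)) {
    prof <- invert_clock(target, ref2, clock)
    expect_equal(compute_dnam_age(prof, clock), target, tolerance = 1e-9)
  }
})

test_that("inversion shifts along the coefficient direction with least norm", {
  clock <- default_clock()
  set.seed(41)
  ref <- random_profile()
  cur <- compute_dnam_age(ref, clock)
  prof <- invert_clock(cur + 3, ref, clock)
  shift <- as.numeric(prof - ref)
  coefs <- clock$sites$coefficient
  # ||c||^2 frozen from an independent decimal computation
  expect_equal(sum(coefs^2), 1.1864904940808751, tolerance = 1e-12)
  expect_equal(shift, 3 * coefs / 1.1864904940808751, tolerance = 1e-9)
  # per unit age change the move along the gradient has length 1/||c||
  expect_equal(sqrt(sum((shift / 3)^2)), 1 / sqrt(sum(coefs^2)),
               tolerance = 1e-9)
})

test_that("infeasible inversion targets name the binding site", {
  ref <- stats::setNames(rep(50, 5), clock_genes)
  expect_error(invert_clock(200, ref), "methC1-KLF14")
  expect_error(invert_clock(-150, ref), "infeasible")
})

test_that("a noiseless null cohort yields zero acceleration end to end", {
  p <- cohort_params(sigma_subject = 0, sigma_resid = 0, treatment_shift = 0,
                     igf_slope = 0, site_noise_sd = 0)
  co <- generate_cohort(p, seed = 43)
  d <- co$data
  d$dnam_age <- batch_dnam_age(d)
  acc <- compute_age_acceleration(d, fit_age_regression(d, "pooled"))
  expect_equal(acc$age_accel, rep(0, nrow(d)), tolerance = 1e-8)
})

test_that("default cohorts mirror the intended clinical structure", {
  co <- generate_cohort(cohort_params(n_subjects = 120), seed = 47)
  d <- co$data
  igf0 <- median(d$igf1[d$timepoint == "T0"])
  igf6 <- median(d$igf1[d$timepoint == "T6"])
  expect_gt(igf0, 90); expect_lt(igf0, 160)   # baseline median near 120 ug/L
  expect_gt(igf6 / igf0, 2.2)                 # ~2.8-fold treatment rise
  expect_lt(igf6 / igf0, 3.6)
  d$dnam_age <- batch_dnam_age(d)
  acc <- compute_age_acceleration(d, fit_age_regression(d, "pooled"))
  m0 <- mean(acc$age_accel[acc$timepoint == "T0"])
  expect_gt(m0, 0)                            # treatment lowers acceleration
  expect_equal(m0, -mean(acc$age_accel[acc$timepoint == "T6"]),
               tolerance = 1e-9)
})

test_that("invalid generator parameters are rejected before sampling", {
  expect_error(cohort_params(n_subjects = 2), ">= 3")
  expect_error(cohort_params(sigma_resid = -1), ">= 0")
  expect_error(cohort_params(age_range_t0 = c(15, 6)), "increasing")
  expect_error(cohort_params(site_noise_sd = 20), "\\[0, 100\\]")
})

test_that("recovery reports aggregate estimator behaviour against truth", {
  p <- cohort_params(n_subjects = 40, treatment_shift = -1.8, igf_slope = 0)
  rep1 <- recovery_experiment(p, n_reps = 1, seed = 3)
  expect_identical(nrow(rep1$reps), 1L)
  s1 <- summary(rep1)
  expect_true(is.na(s1$coverage))  # no coverage claim from a single replicate
  rep30 <- recovery_experiment(p, n_reps = 30, seed = 3, covariate = "igf1")
  s30 <- summary(rep30)
  expect_identical(s30$parameter, c("treatment_shift", "igf1_slope"))
  expect_lt(abs(s30$bias[1]), 0.5)
})

test_that("the treatment-shift estimator tightens as the cohort grows", {
  shift <- -1.8
  rmse_at <- function(n) {
    p <- cohort_params(n_subjects = n, treatment_shift = shift, igf_slope = 0)
    summary(recovery_experiment(p, n_reps = 40, seed = 5))$rmse
  }
  r <- c(rmse_at(20), rmse_at(80), rmse_at(320))
  expect_lt(r[3], r[1])
  expect_lt(r[3], 0.25)
})
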