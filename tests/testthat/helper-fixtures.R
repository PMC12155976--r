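# Fixture builders and independent oracles shared across test files.

clock_genes <- c("ELOVL2", "C1orf132", "TRIM59", "KLF14", "FHL2")

# random in-bounds methylation profile
random_profile <- function() {
  stats::setNames(stats::runif(5, 5, 95), clock_genes)
}

# paired cohort whose DNAm ages lie exactly on a given line
line_cohort <- function(n = 10, intercept = 2, slope = 1.1) {
  age0 <- seq(6, 15, length.out = n)
  data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(n)), each = 2),
    timepoint = rep(c("T0", "T6"), n),
    age = as.vector(rbind(age0, age0 + 0.5)),
    dnam_age = as.vector(rbind(intercept + slope * age0,
                               intercept + slope * (age0 + 0.5)))
  )
}

# paired cohort with arbitrary response values (recycled over rows)
paired_cohort <- function(accel, n = length(accel) / 2, extra = NULL) {
  df <- data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(n)), each = 2),
    timepoint = rep(c("T0", "T6"), n),
    age_accel = accel
  )
  if (!is.null(extra)) df <- cbind(df, extra)
  df
}

# brute-force Wilcoxon signed-rank oracle: two-sided exact p over every
# sign assignment (expand.grid enumeration, independent of the package's
# convolution code)
brute_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  w <- sum(ranks[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% ranks)
  p_low <- mean(w_all <= w + 1e-12)
  p_high <- mean(w_all >= w - 1e-12)
  min(1, 2 * min(p_low, p_high))
}

# brute-force Spearman permutation oracle (all n! permutations)
brute_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(perms(ry), function(p) stats::cor(rx, p), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}
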