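# epiaccel

Epigenetic age acceleration for paired pre/post-treatment cohorts.

`epiaccel` is built for a small but common clinical-epigenomics design:
a cohort measured before (T0) and after (T6) an intervention — the
motivating setting is growth-hormone-deficient (GHD) children treated
with recombinant human growth hormone (rhGH) for six months — where the
question is whether treatment changes *biological* age beyond what the
calendar explains, and how that change relates to clinical covariates
such as circulating IGF-1.

The package provides, end to end:

1. **A five-CpG DNAm-age clock.** Biological age in years is an affine
   function of percent methylation at five CpG sites:

   ```
   Y = b0 + b1·meth(ELOVL2) + b2·meth(C1orf132/MIR29B2C)
          + b3·meth(TRIM59) + b4·meth(KLF14) + b5·meth(FHL2)
   ```

   with the published intercept and coefficients carried verbatim at
   full precision in a data file (`default_clock()`), never retyped in
   code. Methylation enters in percentage points on [0, 100];
   out-of-range values are errors, not clamped.

2. **Residual-based age acceleration.** The residual of DNAm age from
   an OLS regression of DNAm age on chronological age
   (`fit_age_regression()` + `compute_age_acceleration()`). Positive
   values mean biologically older than expected; by construction the
   residuals sum to zero and are uncorrelated with chronological age
   over the fitting scope. With both timepoints pooled and complete
   pairs, the T0 and T6 mean accelerations are exactly equal in
   magnitude and opposite in sign.

3. **Paired descriptive statistics.** Paired t and exact Wilcoxon
   signed-rank tests (the exact two-sided p is computed from the full
   distribution over all 2^n sign assignments, valid under mid-rank
   ties), Spearman correlations with exact small-sample p, HOMA-IR,
   and a normality-policy-driven baseline-vs-follow-up summary table
   (`summarize_cohort()`).

4. **Random-intercept mixed models** (REML, via lme4 internally):
   * `fit_change_model()` — the T6 − T0 contrast on acceleration,
     univariate or covariate-adjusted; on complete pairs the univariate
     contrast equals the paired mean difference.
   * `fit_interaction_model()` — treatment × covariate effect
     modification, reporting the covariate effect separately at T0 and
     at T6 (main effect, and main + interaction with its combined SE).
   * `fit_adjusted_model()` — the covariate association adjusted for
     treatment.
   * `marginal_means()` — model-predicted mean acceleration per
     timepoint with the covariate fixed at a chosen value (e.g. IGF-1
     at its baseline median), CIs from the fixed-effects covariance.

5. **A synthetic cohort generator with known ground truth**
   (`generate_cohort()`, `recovery_experiment()`): complete T0/T6 pairs
   with a subject random intercept, a treatment shift, an IGF-1 slope,
   and methylation back-solved through the clock so the clock
   reproduces each intended DNAm age exactly — so every pipeline stage
   is testable, with bias/RMSE/coverage/rejection reports against the
   generative truth.

## Worked example

```r
library(epiaccel)

cohort <- generate_cohort(cohort_params(), seed = 42)   # 10 subjects, T0/T6
d <- cohort$data
d$dnam_age <- batch_dnam_age(d)                         # five-CpG clock
fit <- fit_age_regression(d, scope = "pooled")
d <- compute_age_acceleration(d, fit)

age_correlations(d)
#>   timepoint       rho     p_value  n
#> 1        T0 0.6848485 0.035091538 10
#> 2        T6 0.8787879 0.001977059 10

fit_change_model(d)                                     # univariate
#>     term      beta        se    ci_low   ci_high df    p_value
#>  T6 - T0 -1.710635 0.9427008 -3.691176 0.2699059 18 0.08628605

fit_change_model(d, covariate = "igf1")                 # IGF-1-adjusted
#>     term      beta       se    ci_low   ci_high df     p_value
#>  T6 - T0 -3.816597 1.125686 -6.191586 -1.441608 17 0.003478827

marginal_means(d, "igf1", 120)
#>  timepoint       mean        se     ci_low    ci_high
#>         T0  0.8004666 0.7189852 -0.7164596  2.3173927
#>         T6 -3.0161304 1.0277662 -5.1845276 -0.8477332
#>   T6 vs T0 comparison p = 0.003479
```

Chronological and DNAm ages correlate at both visits; the raw treatment
contrast on acceleration is negative but not significant, and becomes
clearly negative once IGF-1 is adjusted for — the generator's default
truth (an IGF-adjusted shift of −4.137 years with a positive IGF-1
slope of 0.011 years per µg/L) is what the models recover here. The
marginal means show the same contrast as model-predicted group means at
IGF-1 = 120 µg/L.

The whole battery — paired summary table, per-timepoint correlations,
change/interaction/adjusted models and marginal means, written as CSVs
— runs in one call:

```r
log <- run_pipeline(d, pipeline_config(), "results/")
```

A thin command-line wrapper with `simulate`, `compute-age`, `accel`,
`report`, `analyze` and `run` subcommands ships in
`inst/scripts/epiaccel.R`.

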