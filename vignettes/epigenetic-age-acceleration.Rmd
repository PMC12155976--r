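---
title: "Methods: epigenetic age acceleration in paired treatment cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic age acceleration in paired treatment cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiaccel)
```

## The measurement model

The clock is a fixed affine map from percent methylation at five CpG
sites (in ELOVL2, C1orf132/MIR29B2C, TRIM59, KLF14 and FHL2) to a
biological age in years. It is *not* re-estimated by this package: the
intercept and the five coefficients are treated as published constants.
To keep the fifteen-digit constants from drifting through transcription
they live in `inst/extdata/clock_5cpg.json` as decimal strings, parsed
once at load and reserialized from the same strings, so a clock round
trips through `write_clock()`/`read_clock()` bit-identically.

Two conventions deserve a note:

* **Units.** Methylation enters in percentage points on [0, 100], not
  as fractions. With an intercept near 3.3 years and coefficients of
  order 0.2–0.8 years per unit, only percent-scale inputs produce ages
  spanning childhood through adulthood; fraction-scale inputs would
  compress the clock's range to a few years. The package therefore
  validates inputs against [0, 100] and treats out-of-range values as
  hard errors — silently clamping would corrupt the score.
* **Site naming.** The formula's site keys (`methC7-ELOVL2`, ...) are
  the canonical identifiers; gene symbols (`ELOVL2`, `MIR29B2C` as an
  alias of the C1orf132 site, ...) map onto them, so tabular inputs can
  use plain gene columns.

## Age acceleration

Age acceleration is the residual of DNAm age from an OLS regression of
DNAm age on chronological age. Residuals over the fitting scope sum to
zero and are uncorrelated with chronological age — the property that
makes "acceleration" interpretable independently of the calendar — and
both identities are enforced by tests at 1e-9.

**Scope of the regression.** With two visits per subject the line can
be fitted on the pooled observations or on baseline only. Pooling is
the default here: with complete pairs it forces the T0 and T6 group
means of acceleration to be exactly equal in magnitude and opposite in
sign, which is the structure one sees in paired cohort summaries of
this design, and it uses all the data for the nuisance line.
`baseline_only` is kept as an option for scoring follow-up data against
a baseline-frozen line; residuals are always computed against the fit's
*stored* coefficients rather than refit, so frozen scoring is
reproducible.

## Paired descriptive statistics

`summarize_cohort()` routes each numeric variable by a normality
policy: Shapiro–Wilk on the pooled T0+T6 values at alpha = 0.05 selects
the paired t-test (summarised mean ± SD) when normality is not
rejected, else the Wilcoxon signed-rank test (summarised median
[Q1;Q3]). The policy is a package choice — display conventions in
published tables imply the routing but rarely state the normality test
— so per-variable overrides let a user force either route. Categorical
variables are tabulated without a test. Degenerate pairings (all
differences equal, e.g. a visit interval that is constant by design)
are reported with `NA` statistics instead of aborting the table.

Numerical conventions, fixed once:

* **Wilcoxon zeros and ties.** Zero differences are dropped before
  ranking (the original signed-rank procedure); ties get mid-ranks.
  The exact two-sided p is computed from the full distribution of W
  over all 2^n sign assignments — implemented as an integer
  convolution over doubled ranks so tied (half-integer) mid-ranks are
  handled exactly — and is available up to n = 25 nonzero differences.
  The two-sided p is `min(1, 2·min(P(W ≤ w), P(W ≥ w)))`. The normal
  approximation (with tie correction) serves larger n.
* **Spearman.** rho is the Pearson correlation of mid-ranks. The p is
  the exact permutation p when n ≤ 10 and there are no ties (delegated
  to R's exact algorithm; verified in tests against brute-force
  enumeration of all permutations at small n), otherwise the t
  approximation on n − 2 df.
* **Quartiles** for the [Q1;Q3] display use type-7 linear
  interpolation, R's default.
* **HOMA-IR** converts glucose mg/dL → mmol/L by dividing by 18.016
  (the molar mass of glucose); rounded legend factors like "1 mg/dL =
  0.06 mmol/L" are not usable arithmetic.

## The longitudinal inference battery

All models are linear mixed-effects regressions for paired data with a
random intercept per subject, fitted by REML (lme4 behind the module
surface):

* change model: `accel ~ time (+ covariate) + (1 | subject)`;
* interaction model: `accel ~ time * covariate + (1 | subject)`;
* adjusted model: `accel ~ time + covariate + (1 | subject)`.

Time is coded 0/1 with T0 as reference, so the `time` coefficient *is*
the T6 − T0 difference. On complete pairs the univariate change
contrast equals the paired mean difference exactly (a balanced-design
identity, checked numerically at 1e-6). In the interaction model the
covariate effect "at T0" is the main effect and "at T6" is main +
interaction, with the SE of the linear combination taken from the
fixed-effects covariance; the identity `effect_at_T6 = covariate beta +
interaction beta` holds by construction and is asserted in tests.

**Degrees of freedom.** Wald t tests and CIs (`beta ± t(df, 0.975)·SE`)
need a df convention, and mixed-model software differs. The default is
residual df (observations minus fixed-effect parameters), a simple
between-within-style choice; Satterthwaite (via lmerTest) can be
swapped in through `df_method` without changing the estimates. With
balanced pairs and moderate n the practical difference is small, but
the choice is surfaced rather than hidden.

**Marginal means** are linear predictions at time 0/1 with the
covariate held at a fixed value (e.g. IGF-1 at its baseline median);
their difference is exactly the adjusted time contrast and the
comparison p is the contrast's p. A fixed value outside the observed
covariate range warns (extrapolation) but does not error. In tests the
means are cross-checked against an independent emmeans computation.
The IGF-1 reference value is exposed as a parameter (`marginal` in
`pipeline_config()`, default 120 µg/L) rather than hard-coded, since a
"baseline median" is cohort-specific.

Covariates enter untransformed and uncentered, so betas are per raw
unit (e.g. years of acceleration per µg/L IGF-1). No multiple-testing
correction is applied across a covariate battery; when many covariates
are screened the per-covariate p-values should be read accordingly.

## The synthetic cohort generator

Individual-level data for this design are rarely shareable, so the
generator is a first-class module: every pipeline stage is exercised
against cohorts whose ground truth is known.

Per subject *i* and timepoint *t*:

```
accel_it = u_i + shift·1[t = T6] + slope_t·(IGF_it − IGF_ref) + e_it
u_i ~ N(0, sigma_subject²),  e_it ~ N(0, sigma_resid²)
DNAm_it = age_it + accel_it
```

with baseline age uniform on 6–15 years, the second visit 6 months
later, IGF-1 log-normal (baseline median 120.5 µg/L, sdlog 0.4) and
multiplied by 2.8 (with log-scale noise 0.3) at T6. Defaults:
`treatment_shift = -4.137` years (the IGF-adjusted contrast),
`igf_slope = 0.011` years per µg/L, `sigma_subject = sigma_resid = 2`
years (total cross-sectional SD ≈ 2.8 years). These defaults are
anchored to the published cohort summaries of the motivating GHD study
design; the marginal (unadjusted) T6 − T0 difference implied by them is
about −1.7 years because the IGF-1 rise pushes acceleration up while
treatment pushes it down. An optional `igf_slope_change` lets the IGF-1
slope differ at T6 for effect-modification experiments.

Methylation is *back-solved*: a reference profile per observation
(linear site trajectories plus Gaussian site noise) is shifted along
the clock's coefficient direction — the minimum-norm solution, all five
sites moving in proportion to their coefficients — until the clock
evaluates exactly to the intended DNAm age (`invert_clock()`, exact to
1e-9; infeasible targets error naming the binding site). Site
trajectory levels and slopes are synthetic conventions: no site-level
methylation summaries exist to anchor them, so they are chosen to keep
values well inside [0, 100] over ages 6–16 and to make the clock track
chronological age roughly 1:1. Base levels are set so the clock
evaluated at the base profile is ≈ 0 years, which keeps the inversion
shift proportional to the target acceleration alone. Assay physics
(bisulfite conversion efficiency, pyrosequencing noise spectra) is not
modelled — site noise is Gaussian — so passing tests say nothing about
robustness to assay artefacts, batch effects or cell-composition
shifts in real blood.

Reproducibility: one master seed spawns a per-subject (and in
`recovery_experiment()` a per-replicate) seed stream, so draws do not
depend on subject order and regeneration is byte-stable.

## Calibration experiments and problem sizes

`recovery_experiment()` runs generate → clock → residual regression →
mixed model per replicate and aggregates bias, RMSE, 95% CI coverage
and rejection rates against the generative truth. The package's own
verification battery uses: 500 replicates of 200 subjects
(sigma_subject = sigma_resid = 2, shift = −1.8, no IGF effect) for
unbiasedness (|bias| < 0.05 years) and coverage (93–97%), and 1000
replicates with a null IGF-1 slope for type-I calibration (rejection
within 3.5–6.5%). Consistency is checked at n = 20/80/320. Coverage and
rejection are reported only from ≥ 100 replicates; below that the
report abstains. Replicate-level model failures are recorded rather
than fatal, but an experiment with > 5% failures errors out.

## Degenerate inputs and numerical edges

* Constant covariates and rank-deficient designs are rejected before
  fitting ("singular design"), not silently dropped.
* A perfectly deterministic response (zero residual variance) yields
  exact point estimates; the covariance of the fixed effects is not
  estimable there and SEs are reported as zero/NA rather than invented.
* Boundary (singular random-effect variance) fits are returned with a
  flag, not errors — with n = 10 subjects they are a real possibility.
* The residual regression requires ≥ 3 observations and non-constant
  chronological age.
* Pipeline outputs contain no timestamps, so reruns on identical input
  and configuration are byte-identical.

## Known limitations

* The clock is consumed as published; no uncertainty in its
  coefficients is propagated.
* Residual-based acceleration estimates the expected-age line from the
  analysis cohort itself; with n = 10 subjects that line is noisy, and
  the mixed-model SEs do not account for its estimation.
* The df convention for Wald tests is a choice (see above); exact
  replication of results produced by other software additionally
  depends on their covariance estimator and df options.
* The generator emulates the *statistical* structure of the design,
  not the biology or the assay; parameter-recovery results certify the
  estimators, not any claim about real cohorts.
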