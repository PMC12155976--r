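Package: epiaccel
Title: Epigenetic Age Acceleration in Paired Pre/Post-Treatment Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes DNA-methylation (DNAm) age from a five-CpG linear
    epigenetic clock (ELOVL2, C1orf132/MIR29B2C, FHL2, KLF14, TRIM59),
    derives residual-based epigenetic age acceleration from a regression
    of DNAm age on chronological age, and runs a longitudinal inference
    battery for paired pre/post-treatment designs: random-intercept mixed
    models for the treatment contrast, covariate adjustment, treatment-by-
    covariate effect modification, and covariate-fixed marginal means.
    Includes paired descriptive statistics (paired t, exact Wilcoxon
    signed-rank, Spearman correlation, HOMA-IR) and a synthetic cohort
    generator with known ground truth for parameter-recovery and
    calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    emmeans,
    lmerTest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
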