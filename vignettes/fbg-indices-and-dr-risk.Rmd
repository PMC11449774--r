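---
title: "Visit-to-visit FBG indices and retinopathy risk-model comparison: methods"
author: "fbgload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visit-to-visit FBG indices and retinopathy risk-model comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbgload)
```

## The scientific problem

Single fasting blood glucose (FBG) measurements are noisy snapshots of
glycemic control, and diabetic retinopathy (DR) is driven by *chronic*
glycemic exposure. When a cohort is screened repeatedly over years, the
visit-to-visit FBG trajectory supports a family of summary indices that
capture level, variability, or both:

* **SD** and **CV** — the sample standard deviation of a participant's FBG
  values, and the same normalised by the mean (in %). Sample (n − 1)
  denominators are used throughout; this is the usual convention for
  visit-to-visit variability work.
* **VIM** (variation independent of the mean) — `100 * SD / mean^beta`,
  where the exponent `beta` is the OLS slope of `ln(SD)` on `ln(mean)`
  across the cohort. By construction VIM is (rank-)uncorrelated with the
  mean, so it isolates variability from level. `beta` is a *cohort-level*
  quantity: VIM values are only comparable within the cohort they were
  calibrated on. Participants with SD = 0 cannot enter the log-log fit and
  are assigned VIM = 0; a wholly constant cohort leaves `beta` undefined
  (recorded as `NA`) with every VIM 0.
* **ARV** (average real variability) — the mean absolute difference between
  consecutive visits, the only variability index sensitive to visit order.
  Cohort tables conventionally report ARV in % of the mean, so both the
  mmol/L value (`arv`) and the normalised one (`arv_pct`) are computed; the
  pipeline's association and comparison tables use `arv_pct`. (Reported
  cohort summaries for ARV carry a "%" unit with magnitudes incompatible
  with mmol/L, so the normalised variant is the default; both remain
  available.)
* **M-FBG** — the plain mean over visits.
* **Cumulative FBG load** — the fraction (in %) of the time-integrated FBG
  curve that lies *above* the 5.6 mmol/L prediabetes threshold. The
  trajectory is interpolated piecewise-linearly between visits;
  threshold crossings inside a segment are located analytically, so the
  excess area is exact for the interpolant, with no extrapolation beyond
  the participant's own first and last visit. For a constant series at
  level L the closed form is `100 * (1 - 5.6/L)` (0 below threshold), which
  is also how the index behaves for very flat trajectories. A second
  reading of the numerator — the full area under the curve restricted to
  supra-threshold intervals (`method = "supra"`) — is provided because the
  verbal definition of such load indices is ambiguous; the excess-area
  reading is the default since it matches the cumulative-load literature
  and the relative magnitudes reported for DR vs non-DR groups
  (load ≈ 31% at mean FBG ≈ 8.5 ≈ the excess fraction (8.5 − 5.6)/8.5).

Baseline FBG is taken as the *first-visit* value (the alternative, last
visit, is a one-line change in `compute_indices`); visit times are days
since each participant's first visit, because real screening calendars
vary by participant.

## Cohort handling

`read_cohort()` ingests two delimited text files (long-format visits,
one-row-per-participant covariates) and validates the obvious invariants
(positive FBG, unique participant/time pairs, referential integrity).
Comorbidity flags follow the standard clinical definitions — hypertension:
SBP ≥ 140 or DBP ≥ 90 mmHg or self-report or antihypertensive use;
dyslipidemia: LDL-C ≥ 3.37, HDL-C < 1.04, TC ≥ 5.18, or TG ≥ 1.7 mmol/L or
self-report or lipid-lowering use — and a pre-supplied flag always wins over
derivation, mirroring the sufficiency of self-report.

Eligibility filtering retains participants with at least three FBG visits
(inclusive boundary), an FBG test in the final screening window, and a
non-missing DR outcome, counting exclusions per criterion in that order.
The final-window requirement is carried as a per-participant boolean
(`has_final_window_fbg`) rather than a hard-coded calendar range, so real
data can supply it through any date window.

Missing covariates are imputed with the cohort mean (continuous) or the
median of the 0/1 coding (categorical). For binary variables the median
coincides with the mode; an exact tie (median 0.5) rounds down — the tie
rule has to be explicit since "median of a binary coding" is otherwise
undefined at 50/50 splits.

## Association and comparison machinery

The outcome is binary (DR vs no DR), so the logistic model is fitted by
maximum likelihood with `stats::glm`; a two-category multinomial fit would
be identical. Adjusted models use the classical risk factors: age (linear),
sex, BMI, education, income, current smoking, current drinking,
hypertension, dyslipidemia. BMI is included in the adjustment set (the
descriptive convention in this literature lists it among the classical
factors even where running text omits it); this is configurable. Confidence
intervals are Wald (`exp(b ± 1.96 SE)`) rather than profile-likelihood —
cheaper, and the convention in the reporting this package mirrors. Scaling
follows the reporting convention per index: FBG, SD and M-FBG per unit
(mmol/L); CV, VIM, ARV and cumulative load per 1 cohort-SD increase
(`standardize_per_sd`), so that OR_perSD = OR_perUnit^SD.

Perfect separation is detected (degenerate fitted probabilities together
with runaway coefficients) and reported as an error naming the separating
term rather than returning meaningless estimates.

Model discrimination and comparison use:

* **AUC** by the Mann–Whitney estimator (ties count one half), with
  standard errors and paired tests from DeLong's structural-components
  variance. The paired DeLong test is the field standard for correlated ROC
  curves and is what `compare_models()` reports for changes in AUC.
* **IDI** — the difference in discrimination slopes, with the usual
  paired-difference asymptotic SE and an optional seeded bootstrap CI.
* **Categorical NRI** with configurable cut-offs, default `{0.05, 0.15}`
  (the conventional three-category reclassification). The original
  analysis does not disclose its category boundaries, so NRI values here
  are only exercised on synthetic data and the cut sensitivity is exposed
  through the configuration.
* **AIC/BIC** as `-2 logLik + 2k` and `-2 logLik + k ln(n)`.

All p-values are two-sided and no multiplicity correction is applied across
the model grid, matching the analysis being replicated. The grid itself is
the fixed set of 18 specifications (classical-only, classical + each single
index, and ten FBG/load-centred combinations), with "classical + FBG" as
the default reference.

## The synthetic cohort generator

No individual-level data are deposited for the original cohort, so the
package ships a seeded generator whose *defaults are the study conditions*:
5054 participants, five screening waves at days 0/550/1280/2000/2750
(roughly "every one to two years" over eight years), per-wave attendance
0.95/0.85/0.80/0.80/0.85 with at least one attended wave, and a
normoglycemic/prediabetes/diabetes mixture of 0.55/0.35/0.10 with class
FBG levels 5.15/6.10/8.50 mmol/L. These levels and the class person/visit
noise SDs were chosen once so the cohort marginals land near the reported
ones (mean FBG ≈ 5.8, overall SD ≈ 1.2–1.5 mmol/L); covariate prevalences
(52% female, 29% low education, 81% lower income, 17.6% smoking, 21.7%
drinking, 26.5% hypertension, 57.8% dyslipidemia, age 46.3 (11.4), BMI
24.6 (3.5)) are the published baseline ones. Binary covariates with an
age/sex/BMI dependence have their intercepts calibrated by root-finding so
the realised expected prevalence equals the target exactly, whatever the
drawn covariates.

The DR outcome is generated from a logistic model on the participant's
*true* cumulative load — computed from the complete five-wave latent
trajectory before attendance masking — plus the classical covariates, with
the intercept again calibrated so expected prevalence is 3.1%. Generating
the outcome from the load (0.08 log-odds per load-%, ≈ 2.4 odds per load-SD)
rather than from a variability index gives the model-comparison machinery a
known truth: models containing cumulative load *should* dominate, and the
acceptance checks verify they do. Alternative drivers (`m_fbg`, `sd`) are
selectable to probe the comparison machinery under different truths. Visit
noise is independent across waves by default with an AR(1) option, since
real glycemia is autocorrelated; FBG is floored at 3.0 mmol/L because
fasting values below that are vanishingly rare in a general screening
population.

What the generator does *not* emulate: the real joint covariate
distribution beyond simple marginals and mild dependencies, assay error
structure, informative dropout (attendance is independent of glycemia), or
any direct effect of variability on DR. Passing tests therefore demonstrate
correctness and internal consistency of the machinery — not that the
original cohort's exact ORs or AUCs are reproduced, which is impossible
without the data.

## Numerical choices and problem sizes

* Cumulative-load integration is exact for the piecewise-linear
  interpolant; the test suite checks it against a dense-grid trapezoid
  oracle at 1e-6 relative error and against constant-series closed forms.
* SD/CV/ARV/M-FBG are checked against brute-force oracles at 1e-12.
* The paired DeLong test's empirical type-I error is checked against
  [0.03, 0.07] at alpha = 0.05 over 1000 null simulations (n = 200,
  50 cases).
* Wald coverage is checked over 200 replicates at n = 5000.
* Generator calibration is checked over 50 seeds at the default n = 5054
  (mean DR prevalence in [2, 5]%, mean FBG in [5.5, 6.1] mmol/L), and
  recovery of the generating load coefficient within 10% at n = 50 000 —
  attenuation from computing the load on attended visits only (vs the full
  latent trajectory) is negligible because observed and true load correlate
  at ≈ 0.995 under default attendance.
* These sizes keep the whole suite under about a minute while leaving the
  Monte-Carlo error well below every tolerance tested.

Degenerate inputs are errors, not silent NAs: series shorter than two
visits, non-increasing times, single-class outcomes, zero cohort SD in
per-SD scaling, all-missing covariates, and a reference model absent from a
comparison all fail loudly with the offending quantity named. The one
deliberate softening is the all-constant cohort, where every variability
index is legitimately zero and `compute_indices` records an empty VIM
calibration instead of failing.

## Known limitations

* VIM (and hence its associations) depends on the cohort used for
  calibration; merging cohorts requires re-calibration.
* The categorical NRI is sensitive to its cut-offs, which are unknown for
  the original analysis; treat NRI magnitudes as internally comparable
  only.
* The pipeline's in-sample AUCs are optimistic in the usual sense; no
  cross-validation or optimism correction is attempted, matching the
  analysis being mirrored.
* Real-data ingestion is limited to the documented delimited-text contract;
  ophthalmic grading is out of scope — DR enters as a binary label.

## A worked run

```{r example, eval = FALSE}
cfg <- run_config(params = cohort_params(n_participants = 2000L),
                  seed = 7, outdir = "fbgload_out")
res <- run_full_analysis(cfg)
res$table3_discrimination[, c("model", "auc", "delta_auc", "delta_auc_p")]
```

The emitted tables mirror a cohort paper's structure: baseline
characteristics by DR group (t/Wilcoxon for continuous variables, with the
Shapiro–Wilk check at alpha 0.05 deciding which, chi-square/Fisher with the
expected-cell < 5 rule for categorical ones — the originals name both tests
but not their selection rule, so these conventional rules are ours), crude
and age/sex-adjusted Spearman correlations among indices (the adjusted
version is a partial correlation on ranks), the per-index association
table, and the 18-model discrimination/reclassification/information-criteria
comparison, repeated for the ≥3, ≥4 and =5-visit sensitivity subsets.
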