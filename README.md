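# fbgload

Visit-to-visit fasting blood glucose (FBG) indices and a diabetic
retinopathy (DR) risk-model comparison pipeline, for epidemiologists
working with longitudinal screening cohorts.

A single FBG measurement is a snapshot; DR risk tracks *chronic* glycemic
exposure. Given each participant's repeated FBG values over screening
waves, `fbgload` computes the seven standard trajectory summaries,

* baseline (first-visit) FBG,
* **SD** — sample standard deviation of the visit values,
* **CV** = 100 · SD / mean (%),
* **VIM** = 100 · SD / mean^β, with β the cohort-wide OLS slope of ln SD
  on ln mean, so VIM is uncorrelated with the mean,
* **ARV** — mean |difference| between consecutive visits (also as % of
  mean),
* **M-FBG** — the mean over visits,
* **cumulative FBG load** — 100 · (area of the piecewise-linear FBG curve
  above the 5.6 mmol/L prediabetes threshold) / (total area under the
  curve), with threshold crossings located analytically,

and then compares logistic DR-prediction models built from them:
covariate-adjusted odds ratios (Wald CIs), AUC with DeLong variance and
the paired DeLong test for ΔAUC, integrated discrimination improvement
(IDI), categorical net reclassification (NRI), and AIC/BIC, over an
18-model grid (classical risk factors alone, + each single index, + ten
index combinations). Cohort plumbing — validation, clinical
hypertension/dyslipidemia derivation, eligibility filters (≥3 visits,
final-window test, gradable outcome), mean/median imputation — and a
seeded synthetic longitudinal cohort generator are included, so the whole
pipeline is testable without access to any real cohort.

## Worked example

```r
library(fbgload)
cfg <- run_config(params = cohort_params(n_participants = 2000L),
                  seed = 7, outdir = "fbgload_out")
res <- run_full_analysis(cfg)
```

On this synthetic cohort (2000 participants, DR generated from cumulative
load plus classical risk factors) the fitted VIM exponent is β = 1.861,
and the association table (`res$table2_associations`) reads:

```
         term       scaling        adjusted_or
 fbg_baseline      per_unit   2.26 (1.86-2.73)
           sd      per_unit 10.43 (5.06-21.48)
        m_fbg      per_unit   2.30 (1.91-2.76)
           cv per_cohort_sd   1.59 (1.24-2.04)
          vim per_cohort_sd   1.02 (0.75-1.39)
      arv_pct per_cohort_sd   1.50 (1.17-1.92)
     cum_load per_cohort_sd   2.77 (2.19-3.49)
```

Each row is the odds of DR per unit (mmol/L) or per 1 cohort-SD increase
of that index, adjusted for age, sex, BMI, education, income, smoking,
drinking, hypertension and dyslipidemia. As designed into the generator,
cumulative load carries the strongest per-SD association while VIM — pure
variability, decorrelated from level — carries none. The discrimination
table (`res$table3_discrimination`, reference model "classical + FBG"):

```
                                                    model    auc delta_auc       p
                             Classical risk factors + FBG 0.9196   +0.0000 1.0e+00
                                   Classical risk factors 0.8040   -0.1155 9.0e-06
             Classical risk factors + cumulative FBG load 0.9022   -0.0173 6.9e-02
 Classical risk factors + FBG + ARV + cumulative FBG load 0.9178   -0.0018 6.7e-01
```

i.e. adding any glycemic-level index to the classical factors raises the
AUC by ≈0.10–0.12, after which further indices move it by fractions of a
point — the qualitative pattern such cohort analyses report.
`res$table4_reclassification` holds the matching IDI/NRI rows and
`res$aic_bic` the information criteria; sensitivity re-runs restricted to
participants with ≥4 and =5 visits are emitted alongside.

A thin command-line front end is installed at `inst/cli/fbgload`
(`simulate`, `indices`, `analyze` subcommands over the same functions).

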