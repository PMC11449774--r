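Package: fbgload
Title: Visit-to-Visit Fasting Blood Glucose Indices and Retinopathy Risk Model Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-participant visit-to-visit fasting blood glucose
    (FBG) indices from longitudinal cohort data: standard deviation,
    coefficient of variation, variation independent of the mean (with
    cohort-wide exponent calibration), average real variability, mean FBG,
    and the cumulative FBG load (the share of the time-integrated glucose
    curve above the 5.6 mmol/L prediabetes threshold). Provides a diabetic
    retinopathy risk-model comparison pipeline: covariate-adjusted logistic
    associations, AUC with DeLong variance and paired tests, integrated
    discrimination improvement, categorical net reclassification, and
    AIC/BIC over a grid of candidate models, plus a seeded synthetic
    longitudinal cohort generator for testing every stage without access to
    the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
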