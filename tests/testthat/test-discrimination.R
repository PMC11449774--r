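# AUC / DeLong machinery, IDI, categorical NRI, information criteria.

test_that("AUC equals the pair-enumeration oracle, including ties", {
  y <- rep(c(1L, 0L), c(8, 12))
  withr::local_seed(31)
  r <- round(runif(20), 1)  # coarse rounding forces ties
  got <- auc_delong(r, y)
  expect_equal(unname(got["auc"]), oracle_auc(r, y), tolerance = 1e-12)

  # perfect separation and degenerate scores
  expect_equal(unname(auc_delong(y + 0, y)["auc"]), 1.0)
  expect_equal(unname(auc_delong(rep(0.4, 20), y)["auc"]), 0.5)
  expect_error(auc_delong(r, rep(1L, 20)), "both outcome classes")

  # random instances up to n = 200
  for (i in 1:20) {
    n <- sample(10:200, 1)
    y2 <- rbinom(n, 1, 0.3)
    if (length(unique(y2)) < 2) next
    r2 <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    expect_equal(unname(auc_delong(r2, y2)["auc"]), oracle_auc(r2, y2),
                 tolerance = 1e-12)
  }
})

test_that("DeLong SE and paired test agree with pROC", {
  skip_if_not_installed("pROC")
  withr::local_seed(32)
  n <- 120
  y <- rbinom(n, 1, 0.35)
  r1 <- plogis(y + rnorm(n))
  r2 <- plogis(y + rnorm(n))

  got <- auc_delong(r1, y)
  ro <- pROC::roc(y, r1, quiet = TRUE, direction = "<")
  expect_equal(unname(got["auc"]), as.numeric(pROC::auc(ro)),
               tolerance = 1e-12)
  expect_equal(unname(got["se"]), sqrt(pROC::var(ro, method = "delong")),
               tolerance = 1e-10)

  tst <- delong_test(r1, r2, y)
  ref <- pROC::roc.test(pROC::roc(y, r1, quiet = TRUE, direction = "<"),
                        pROC::roc(y, r2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(unname(tst["p"]), ref$p.value, tolerance = 1e-10)
})

test_that("the paired DeLong test is rank-invariant and null on identity", {
  withr::local_seed(33)
  n <- 80
  y <- rbinom(n, 1, 0.3)
  r <- plogis(y * 0.8 + rnorm(n))
  same <- delong_test(r, r, y)
  expect_equal(unname(same["delta_auc"]), 0)
  expect_equal(unname(same["p"]), 1)
  # strictly monotone transform leaves the AUC untouched
  mono <- delong_test(plogis(5 * qlogis(r) + 1), r, y)
  expect_equal(unname(mono["delta_auc"]), 0)
  expect_error(delong_test(r[-1], r, y), "differ in length")
})

test_that("IDI matches hand arithmetic and the direct-formula oracle", {
  y <- c(1, 1, 0, 0)
  old <- c(0.2, 0.4, 0.1, 0.3)
  new <- c(0.3, 0.5, 0.1, 0.3)
  expect_equal(unname(compute_idi(new, old, y)["idi"]), 0.1)
  expect_equal(unname(compute_idi(old, old, y)["idi"]), 0)

  withr::local_seed(34)
  for (i in 1:20) {
    n <- 60
    yy <- rbinom(n, 1, 0.4)
    if (length(unique(yy)) < 2) next
    a <- runif(n); b <- runif(n)
    got <- compute_idi(a, b, yy)
    expect_equal(unname(got["idi"]), oracle_idi(a, b, yy), tolerance = 1e-12)
    # antisymmetry under swapping new and old
    expect_equal(unname(compute_idi(b, a, yy)["idi"]),
                 -unname(got["idi"]), tolerance = 1e-12)
  }

  # seeded bootstrap CI is reproducible and brackets the estimate
  n <- 200; yy <- rep(c(1, 0), c(50, 150))
  a <- plogis(yy + rnorm(n)); b <- plogis(0.5 * yy + rnorm(n))
  b1 <- compute_idi(a, b, yy, boot = 200, boot_seed = 9)
  b2 <- compute_idi(a, b, yy, boot = 200, boot_seed = 9)
  expect_equal(b1, b2)
  expect_lt(b1["ci_low"], b1["ci_high"])
})

test_that("categorical NRI matches a hand-tabulated 3-category example", {
  # categories [0,0.05), [0.05,0.15), [0.15,1)
  # cases: 4 up, 1 down, 1 same; controls: 1 up, 3 down, 3 same
  y <- rep(c(1, 0), c(6, 7))
  old <- c(0.02, 0.04, 0.10, 0.12, 0.20, 0.08,   # cases
           0.02, 0.06, 0.20, 0.18, 0.30, 0.04, 0.10)
  new <- c(0.06, 0.20, 0.16, 0.30, 0.10, 0.08,   # 4 up, 1 down, 1 same
           0.10, 0.06, 0.10, 0.02, 0.14, 0.04, 0.10)
  res <- nri_categorical(new, old, y)
  expect_equal(unname(res$estimate["nri_cases"]), (4 - 1) / 6)
  expect_equal(unname(res$estimate["nri_controls"]), (3 - 1) / 7)
  expect_equal(unname(res$estimate["nri"]), 3 / 6 + 2 / 7)
  # the reclassification tables account for everyone
  expect_equal(sum(res$reclassification$cases), 6)
  expect_equal(sum(res$reclassification$controls), 7)

  # no movement -> 0; all cases up, controls unchanged -> +1
  none <- nri_categorical(old, old, y)
  expect_equal(unname(none$estimate["nri"]), 0)
  y2 <- rep(c(1, 0), c(10, 5))
  o2 <- c(rep(0.02, 10), rep(0.02, 5))
  n2 <- c(rep(0.10, 10), rep(0.02, 5))
  expect_equal(unname(nri_categorical(n2, o2, y2)$estimate["nri"]), 1.0)

  # antisymmetry
  swap <- nri_categorical(old, new, y)
  expect_equal(unname(swap$estimate["nri"]), -unname(res$estimate["nri"]))
  expect_error(nri_categorical(new, old, y, cuts = c(0.3, 0.2)),
               "strictly increasing")
  expect_error(nri_categorical(new, old, y, cuts = numeric(0)),
               "at least one")
})

test_that("information criteria match their closed forms", {
  fake <- list(log_likelihood = -100, k = 5, n = 100)
  ic <- information_criteria(fake)
  expect_equal(unname(ic["aic"]), 210)
  expect_equal(unname(ic["bic"]), 200 + 5 * log(100))

  d <- make_analysis_data(800L, seed = 35L)
  fit <- fit_dr_model(d, c("age", "cum_load"))
  ic2 <- information_criteria(fit)
  expect_equal(unname(ic2["aic"]), AIC(fit$fit), tolerance = 1e-10)
  expect_equal(unname(ic2["bic"]), BIC(fit$fit), tolerance = 1e-10)
})

test_that("compare_models returns ordered, self-consistent comparisons", {
  d <- make_analysis_data(1500L, seed = 36L)
  fits <- list(
    reference = fit_dr_model(d, c("age", "sex", "fbg_baseline")),
    load = fit_dr_model(d, c("age", "sex", "cum_load")),
    classical = fit_dr_model(d, c("age", "sex")))
  cmp <- compare_models(fits, reference = "reference")
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$model[1], "reference")
  expect_true(all(cmp[1, c("delta_auc", "idi", "nri",
                           "delta_aic", "delta_bic")] == 0))
  expect_true(all(cmp$auc_ci_low <= cmp$auc & cmp$auc <= cmp$auc_ci_high))
  expect_error(compare_models(fits, reference = "nope"), "not in fits")

  # a monotone transform of the reference risks: delta AUC exactly 0,
  # IDI generally not 0
  mono <- fits$reference
  mono$predicted_risks <- plogis(3 * qlogis(mono$predicted_risks) - 1)
  cmp2 <- compare_models(list(a = fits$reference, b = mono), reference = "a")
  expect_equal(cmp2$delta_auc[2], 0)
  expect_false(isTRUE(all.equal(cmp2$idi[2], 0)))

  # a model with itself: all-zero point estimates
  cmp3 <- compare_models(list(a = fits$load, b = fits$load), reference = "a")
  expect_equal(cmp3$delta_auc[2], 0)
  expect_equal(cmp3$idi[2], 0)
  expect_equal(cmp3$nri[2], 0)
})

test_that("adding a pure-noise predictor barely moves AUC or IDI", {
  withr::local_seed(37)
  d <- make_analysis_data(4000L, seed = 37L)
  d$noise <- rnorm(nrow(d))
  f0 <- fit_dr_model(d, c("age", "sex", "cum_load"))
  f1 <- fit_dr_model(d, c("age", "sex", "cum_load", "noise"))
  cmp <- compare_models(list(base = f0, noisy = f1), reference = "base")
  expect_lt(abs(cmp$delta_auc[2]), 0.01)
  expect_lt(abs(cmp$idi[2]), 0.01)
})
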