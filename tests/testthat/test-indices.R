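# FBG index computations against closed forms and independent oracles.

test_that("SD, CV, ARV, M-FBG match closed forms on simple series", {
  expect_equal(fbg_sd(c(5, 6, 7)), 1.0)
  expect_equal(fbg_sd(rep(6.2, 4)), 0.0)
  expect_error(fbg_sd(5), "at least 2")

  expect_equal(fbg_cv(c(5, 6, 7)), 100 / 6)
  expect_equal(fbg_cv(rep(6.2, 4)), 0)
  x <- c(4.8, 5.9, 7.1, 6.3)
  expect_equal(fbg_cv(3 * x), fbg_cv(x))  # scale invariance

  expect_equal(fbg_arv(c(5, 6, 7)), 1.0)
  expect_equal(fbg_arv(c(5, 7, 5)), 2.0)
  expect_equal(fbg_arv(c(5, 7, 5), percent = TRUE),
               100 * 2 / mean(c(5, 7, 5)))
  expect_error(fbg_arv(5), "at least 2")

  expect_equal(fbg_mean(c(5, 6, 7)), 6.0)
  expect_equal(fbg_mean(4.7), 4.7)
  # mean of a concatenation is the weighted mean of part means
  a <- c(5, 6); b <- c(7, 8, 9)
  expect_equal(fbg_mean(c(a, b)),
               (2 * fbg_mean(a) + 3 * fbg_mean(b)) / 5)
})

test_that("SD and ARV match brute-force oracles on 100 seeded series", {
  withr::local_seed(101)
  for (i in 1:100) {
    s <- random_series(sample(3:8, 1))
    expect_equal(fbg_sd(s$values), oracle_sd(s$values), tolerance = 1e-12)
    expect_equal(fbg_arv(s$values), oracle_arv(s$values), tolerance = 1e-12)
    expect_equal(fbg_cv(s$values),
                 100 * oracle_sd(s$values) / mean(s$values),
                 tolerance = 1e-12)
  }
  expect_equal(fbg_sd(c(4.9, 5.3, 6.1, 7.7)),
               oracle_sd(c(4.9, 5.3, 6.1, 7.7)), tolerance = 1e-12)
})

test_that("cumulative load equals closed forms for constant series", {
  expect_equal(cumulative_load(c(0, 100), c(5.6, 5.6)), 0)
  expect_equal(cumulative_load(c(0, 100, 300), c(11.2, 11.2, 11.2)), 50)
  # constant level L: load = 100 * (1 - thr/L) above threshold, else 0
  for (L in c(3.5, 5.0, 6.3, 9.8)) {
    want <- if (L > 5.6) 100 * (1 - 5.6 / L) else 0
    expect_equal(cumulative_load(c(0, 365, 900), rep(L, 3)), want)
  }
})

test_that("cumulative load handles threshold crossings analytically", {
  # linear rise 4.6 -> 6.6 over 100 days crosses 5.6 at t = 50;
  # excess triangle 25, total trapezoid 560
  expect_equal(cumulative_load(c(0, 100), c(4.6, 6.6)), 100 * 25 / 560)
  expect_equal(cumulative_load(c(0, 100), c(6.6, 4.6)), 100 * 25 / 560)
  expect_error(cumulative_load(c(0, 0), c(5, 6)), "strictly increasing")
  expect_error(cumulative_load(100, 5.8), "at least 2")
})

test_that("cumulative load matches a dense-grid integration oracle", {
  withr::local_seed(202)
  for (i in 1:100) {
    s <- random_series(sample(3:7, 1))
    got <- cumulative_load(s$times, s$values)
    want <- oracle_load(s$times, s$values)
    if (want > 0) expect_equal(got, want, tolerance = 1e-6)
    else expect_lt(got, 1e-6)
  }
})

test_that("cumulative load is invariant to collinear midpoints and monotone", {
  withr::local_seed(303)
  s <- random_series(4)
  # insert the exact midpoint of segment 2
  tm <- (s$times[2] + s$times[3]) / 2
  vm <- (s$values[2] + s$values[3]) / 2
  t2 <- sort(c(s$times, tm))
  v2 <- append(s$values, vm, after = 2)
  expect_equal(cumulative_load(t2, v2),
               cumulative_load(s$times, s$values), tolerance = 1e-12)

  # raising any single value never decreases the load
  base <- cumulative_load(s$times, s$values)
  for (j in seq_along(s$values)) {
    v <- s$values; v[j] <- v[j] + 1.5
    expect_gte(cumulative_load(s$times, v), base - 1e-12)
  }

  # zero iff the interpolant never exceeds the threshold
  expect_equal(cumulative_load(c(0, 300, 700), c(4.1, 5.6, 4.9)), 0)

  # the supra-interval variant counts the full area over supra intervals
  expect_equal(cumulative_load(c(0, 100, 200), c(7, 7, 7), method = "supra"),
               100)
})

test_that("indices are order-sensitive only where they should be", {
  withr::local_seed(404)
  s <- random_series(6)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(fbg_sd(s$values[perm]), fbg_sd(s$values))
  expect_equal(fbg_cv(s$values[perm]), fbg_cv(s$values))
  expect_equal(fbg_mean(s$values[perm]), fbg_mean(s$values))
  # counterexamples for ARV and cumulative load
  expect_false(isTRUE(all.equal(fbg_arv(c(5, 7, 5, 7)), fbg_arv(c(5, 5, 7, 7)))))
  expect_false(isTRUE(all.equal(
    cumulative_load(c(0, 10, 500), c(5, 9, 5)),
    cumulative_load(c(0, 10, 500), c(5, 5, 9)))))
})

test_that("VIM calibration recovers exact power laws and reduces to CV", {
  means <- seq(4.5, 9, length.out = 20)
  cal <- fit_vim_calibration(means, 0.3 * means^1.7)
  expect_equal(cal$beta, 1.7, tolerance = 1e-10)
  expect_equal(cal$n_used, 20)

  # beta = 1 makes VIM proportional to CV (equal up to the common factor)
  cal1 <- fit_vim_calibration(means, 0.2 * means)
  expect_equal(cal1$beta, 1, tolerance = 1e-10)
  x <- c(5.2, 6.0, 7.1)
  expect_equal(fbg_vim(sd(x), mean(x), cal1), fbg_cv(x), tolerance = 1e-10)

  # sd = 0 participants are excluded from the fit
  cal2 <- fit_vim_calibration(c(means, 6), c(0.3 * means^1.7, 0))
  expect_equal(cal2$beta, 1.7, tolerance = 1e-10)
  expect_equal(cal2$n_used, 20)
  expect_error(fit_vim_calibration(c(5, 6), c(0, 0)), ">= 2")
  expect_error(fit_vim_calibration(c(6, 6), c(0.5, 0.7)), "degenerate")
})

test_that("VIM beta is recovered from a noisy power-law cohort", {
  withr::local_seed(505)
  n <- 500
  m <- runif(n, 4.5, 9.5)
  s <- exp(log(0.25) + 1.3 * log(m) + rnorm(n, 0, 0.2))
  cal <- fit_vim_calibration(m, s)
  se <- 0.2 / (sd(log(m)) * sqrt(n))   # OLS slope SE, known noise
  expect_lt(abs(cal$beta - 1.3), 4 * se)
})

test_that("cohort-level VIM is decorrelated from the mean", {
  withr::local_seed(606)
  n <- 10000
  m <- runif(n, 4.5, 9.5)
  s <- exp(log(0.25) + 1.4 * log(m) + rnorm(n, 0, 0.3))
  cal <- fit_vim_calibration(m, s)
  vim <- fbg_vim(s, m, cal)
  expect_lt(abs(cor(vim, m, method = "spearman")), 0.1)
})

test_that("compute_indices composes the per-series operations", {
  co <- make_toy_cohort()
  idx <- compute_indices(co)
  expect_equal(nrow(idx), 3)
  for (i in seq_len(3)) {
    id <- idx$participant_id[i]
    v <- co$visits[co$visits$participant_id == id, ]
    expect_equal(idx$sd[i], fbg_sd(v$fbg))
    expect_equal(idx$cv[i], fbg_cv(v$fbg))
    expect_equal(idx$arv[i], fbg_arv(v$fbg))
    expect_equal(idx$m_fbg[i], fbg_mean(v$fbg))
    expect_equal(idx$fbg_baseline[i], v$fbg[1])
    expect_equal(idx$cum_load[i], cumulative_load(v$visit_time, v$fbg))
  }
  cal <- attr(idx, "vim_calibration")
  expect_s3_class(cal, "vim_calibration")
  expect_equal(idx$vim, fbg_vim(idx$sd, idx$m_fbg, cal))

  # constant-FBG cohort: every variability index is exactly zero
  cc <- make_toy_cohort()
  cc$visits$fbg <- rep(c(5.5, 6.5, 8.0), each = 4)
  idx2 <- compute_indices(cc)
  expect_equal(idx2$sd, rep(0, 3))
  expect_equal(idx2$cv, rep(0, 3))
  expect_equal(idx2$vim, rep(0, 3))
  expect_equal(idx2$arv, rep(0, 3))
})

test_that("per-SD standardisation scales as declared", {
  withr::local_seed(707)
  x <- rnorm(200, 10, 2)
  expect_equal(standardize_per_sd(x, "per_unit"), x)
  expect_equal(sd(standardize_per_sd(x, "per_cohort_sd")), 1)
  expect_error(standardize_per_sd(rep(1, 5), "per_cohort_sd"), "SD is zero")
})
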