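# Independent oracles and small fixture builders used across the suite.

# Brute-force two-pass sample SD.
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Explicit successive-difference ARV.
oracle_arv <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s / (length(x) - 1)
}

# Dense-grid numerical integration oracle for the cumulative load:
# piecewise-linear interpolation evaluated on a fine uniform grid, trapezoid
# rule for both the total area and the excess above threshold.
oracle_load <- function(times, values, thr = 5.6, n_grid = 200001L) {
  g <- seq(times[1], times[length(times)], length.out = n_grid)
  f <- approx(times, values, xout = g)$y
  h <- diff(g)
  trap <- function(y) sum(h * (y[-length(y)] + y[-1]) / 2)
  100 * trap(pmax(f - thr, 0)) / trap(f)
}

# O(n^2) pair-enumeration AUC: concordant case-control pairs, ties one half.
oracle_auc <- function(risk, y) {
  cases <- risk[y == 1]
  ctrls <- risk[y == 0]
  s <- 0
  for (a in cases) for (b in ctrls)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(cases) * length(ctrls))
}

# Direct-formula IDI.
oracle_idi <- function(rn, ro, y) {
  (mean(rn[y == 1]) - mean(ro[y == 1])) -
    (mean(rn[y == 0]) - mean(ro[y == 0]))
}

# A tiny hand-built cohort: 3 participants, complete covariates.
make_toy_cohort <- function() {
  visits <- data.frame(
    participant_id = rep(c("A", "B", "C"), each = 4),
    visit_time = rep(c(0, 400, 900, 1500), 3),
    fbg = c(5.0, 5.4, 5.2, 5.6,
            6.2, 6.8, 7.4, 6.5,
            8.1, 9.0, 8.4, 10.2)
  )
  participants <- data.frame(
    participant_id = c("A", "B", "C"),
    age = c(40, 55, 62), sex = c(0L, 1L, 1L),
    education = c(1L, 0L, 0L), income = c(1L, 0L, 0L),
    current_smoking = c(0L, 1L, 0L), current_drinking = c(0L, 1L, 1L),
    hypertension = c(0L, 1L, 1L), dyslipidemia = c(0L, 1L, 1L),
    bmi = c(22.5, 26.0, 27.4),
    dr_status = c(0L, 0L, 1L),
    has_final_window_fbg = c(1L, 1L, 1L)
  )
  fbg_cohort(visits, participants)
}

# Random strictly-increasing FBG series.
random_series <- function(n = 5, fbg_range = c(4, 11)) {
  list(times = cumsum(runif(n, 100, 600)),
       values = runif(n, fbg_range[1], fbg_range[2]))
}

# Small filtered+imputed analysis dataset from the generator.
make_analysis_data <- function(n = 1200L, seed = 11L, scaling = NULL) {
  sc <- simulate_cohort(cohort_params(n_participants = n), seed = seed)
  co <- impute_missing_covariates(apply_eligibility_filters(sc$cohort))
  idx <- compute_indices(co)
  if (is.null(scaling)) scaling <- default_scaling()
  analysis_data(co, idx, scaling = scaling)
}
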