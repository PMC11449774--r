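# Synthetic longitudinal FBG cohort generator.
#
# Emulates a community cohort with ~5 screening waves over ~8 years,
# a normoglycemic / prediabetes / diabetes mixture whose marginals sit near
# the study cohort (mean FBG ~5.8 mmol/L, DR prevalence ~3.1%), and a DR
# outcome generated from the participant's true cumulative FBG load plus
# classical risk factors. The latent truth is retained for recovery tests.

#' Default generator parameters for a synthetic cohort
#'
#' All values have units in their names or documentation; the defaults aim at
#' the marginals of a middle-aged community screening cohort (age 46.3 (11.4)
#' years, 52% female, mean FBG ~5.8 mmol/L, DR prevalence ~3.1%).
#'
#' @param n_participants Cohort size (default 5054).
#' @param wave_times Screening wave times in days since baseline.
#' @param wave_attendance Per-wave attendance probability; at least one
#'   attended wave is forced.
#' @param class_mix Proportions of the normoglycemic / prediabetes / diabetes
#'   latent classes (must sum to 1).
#' @param class_mean Per-class mean FBG level, mmol/L.
#' @param class_person_sd Per-class between-participant SD of the personal
#'   FBG level, mmol/L.
#' @param class_visit_sd Per-class between-visit (within-person) SD, mmol/L.
#' @param class_drift Per-class linear FBG drift, mmol/L per year.
#' @param ar1_rho Lag-1 autocorrelation of the visit noise (0 = independent).
#' @param fbg_floor Lower truncation for generated FBG, mmol/L.
#' @param age_mean,age_sd Age distribution, years (truncated to [18, 90]).
#' @param female_frac Fraction female.
#' @param bmi_mean,bmi_sd BMI distribution, kg/m^2.
#' @param prev_education_low,prev_income_low,prev_smoking,prev_drinking,prev_hypertension,prev_dyslipidemia
#'   Target marginal prevalences; each binary covariate with an age/sex/BMI
#'   dependence has its intercept calibrated so the realised expected
#'   prevalence matches the target.
#' @param dr_prevalence Target DR prevalence; the outcome-model intercept is
#'   calibrated against the realised linear predictors.
#' @param dr_coef Named log-odds per unit of each outcome-model term:
#'   \code{load} (per % of true cumulative FBG load), \code{age} (per year,
#'   centred), \code{male}, \code{smoking}, \code{drinking},
#'   \code{hypertension}, \code{dyslipidemia}, \code{education_low},
#'   \code{income_low}, \code{bmi} (per kg/m^2, centred). Alternative
#'   outcome drivers for probing the comparison machinery: set
#'   \code{dr_driver} to \code{"m_fbg"} or \code{"sd"}.
#' @param dr_driver Glycemic burden term driving the outcome:
#'   \code{"cum_load"} (default), \code{"m_fbg"} or \code{"sd"}.
#' @param dr_missing_prob Probability that the DR outcome is missing
#'   (ungradable photographs).
#' @param load_threshold Threshold for the true cumulative load, mmol/L.
#' @return A list of class \code{cohort_params}.
#' @export
cohort_params <- function(n_participants = 5054L,
                          wave_times = c(0, 550, 1280, 2000, 2750),
                          wave_attendance = c(0.95, 0.85, 0.80, 0.80, 0.85),
                          class_mix = c(normo = 0.55, pre = 0.35, diab = 0.10),
                          class_mean = c(5.15, 6.10, 8.50),
                          class_person_sd = c(0.30, 0.45, 1.20),
                          class_visit_sd = c(0.33, 0.50, 1.10),
                          class_drift = c(0.00, 0.03, 0.10),
                          ar1_rho = 0,
                          fbg_floor = 3.0,
                          age_mean = 46.3, age_sd = 11.4,
                          female_frac = 0.52,
                          bmi_mean = 24.6, bmi_sd = 3.46,
                          prev_education_low = 0.291,
                          prev_income_low = 0.810,
                          prev_smoking = 0.176,
                          prev_drinking = 0.217,
                          prev_hypertension = 0.265,
                          prev_dyslipidemia = 0.578,
                          dr_prevalence = 0.031,
                          dr_coef = c(load = 0.08, age = 0.04, male = 0.45,
                                      smoking = 0.30, drinking = 0.10,
                                      hypertension = 0.55, dyslipidemia = 0.45,
                                      education_low = 0.35, income_low = 0.15,
                                      bmi = 0.04),
                          dr_driver = c("cum_load", "m_fbg", "sd"),
                          dr_missing_prob = 0.02,
                          load_threshold = 5.6) {
  dr_driver <- match.arg(dr_driver)
  p <- mget(setdiff(names(formals()), "dr_driver"))
  p$dr_driver <- dr_driver
  nw <- length(p$wave_times)
  if (p$n_participants < 0) stop("n_participants must be >= 0")
  if (nw < 2L || any(diff(p$wave_times) <= 0))
    stop("wave_times must be an increasing vector of length >= 2")
  if (length(p$wave_attendance) != nw)
    stop("wave_attendance must match wave_times in length")
  if (any(p$wave_attendance < 0 | p$wave_attendance > 1))
    stop("wave_attendance probabilities must lie in [0, 1]")
  if (abs(sum(p$class_mix) - 1) > 1e-8)
    stop("class_mix must sum to 1")
  for (f in c("prev_education_low", "prev_income_low", "prev_smoking",
              "prev_drinking", "prev_hypertension", "prev_dyslipidemia",
              "dr_prevalence", "dr_missing_prob", "female_frac"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (p$load_threshold <= 0) stop("load_threshold must be positive")
  if (abs(p$ar1_rho) >= 1) stop("ar1_rho must lie in (-1, 1)")
  structure(p, class = "cohort_params")
}

# Intercept a such that mean(plogis(a + offset)) == target.
.calibrate_intercept <- function(offset, target) {
  if (target <= 0 || target >= 1) stop("target prevalence must be in (0, 1)")
  f <- function(a) mean(stats::plogis(a + offset)) - target
  stats::uniroot(f, lower = -30, upper = 30, tol = 1e-10)$root
}

# Cumulative load for a matrix of trajectories on a common time grid
# (rows = participants). Vectorised counterpart of cumulative_load().
.cum_load_matrix <- function(times, V, thr) {
  nseg <- length(times) - 1L
  dt <- diff(times)
  a <- V[, -ncol(V), drop = FALSE]
  b <- V[, -1L, drop = FALSE]
  DT <- matrix(dt, nrow(V), nseg, byrow = TRUE)
  total <- rowSums(DT * (a + b) / 2)
  ex <- matrix(.segment_excess(as.vector(a), as.vector(b), as.vector(DT), thr),
               nrow(V), nseg)
  100 * rowSums(ex) / total
}

#' Generate a synthetic FBG cohort
#'
#' Draws covariates, latent glycemic class, a full FBG trajectory over every
#' screening wave, then the DR outcome from a logistic model on the true
#' (full-trajectory) glycemic burden plus covariates, and finally masks the
#' waves the participant did not attend. Regeneration with the same
#' parameters and seed is bit-identical.
#'
#' @param params A \code{\link{cohort_params}} object.
#' @param seed Integer RNG seed.
#' @return An object of class \code{synthetic_cohort}: a list with
#'   \code{cohort} (an \code{fbg_cohort} of the attended visits),
#'   \code{truth} (per-participant latent class, true burden, linear
#'   predictor and outcome probability), \code{params} and \code{seed}.
#' @export
simulate_cohort <- function(params = cohort_params(), seed = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  n <- as.integer(params$n_participants)
  if (n == 0L) {
    empty_p <- data.frame(participant_id = character(0), age = numeric(0),
                          sex = integer(0), bmi = numeric(0),
                          dr_status = integer(0),
                          has_final_window_fbg = integer(0))
    empty_v <- data.frame(participant_id = character(0),
                          visit_time = numeric(0), fbg = numeric(0))
    return(structure(list(cohort = fbg_cohort(empty_v, empty_p),
                          truth = data.frame(), params = params, seed = seed),
                     class = "synthetic_cohort"))
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))

  wt <- params$wave_times
  nw <- length(wt)
  id <- sprintf("P%05d", seq_len(n))

  ## covariates
  age <- pmin(pmax(stats::rnorm(n, params$age_mean, params$age_sd), 18), 90)
  female <- stats::rbinom(n, 1L, params$female_frac)
  male <- 1L - female
  bmi <- pmax(stats::rnorm(n, params$bmi_mean + 0.4 * (male - 0.48),
                           params$bmi_sd), 15)

  bern_cal <- function(target, slope_term) {
    a <- .calibrate_intercept(slope_term, target)
    stats::rbinom(n, 1L, stats::plogis(a + slope_term))
  }
  edu_low <- bern_cal(params$prev_education_low, 0.06 * (age - params$age_mean))
  inc_low <- bern_cal(params$prev_income_low, 0.50 * edu_low)
  smoking <- bern_cal(params$prev_smoking, 2.2 * male)
  drinking <- bern_cal(params$prev_drinking, 2.0 * male)
  htn <- bern_cal(params$prev_hypertension,
                  0.055 * (age - params$age_mean))
  dys <- bern_cal(params$prev_dyslipidemia,
                  0.03 * (age - params$age_mean) + 0.08 * (bmi - params$bmi_mean))

  ## latent glycemic class and full FBG trajectories
  cls <- sample.int(3L, n, replace = TRUE, prob = params$class_mix)
  level <- stats::rnorm(n, params$class_mean[cls], params$class_person_sd[cls])
  eps <- matrix(stats::rnorm(n * nw), n, nw)
  if (params$ar1_rho != 0) {
    rho <- params$ar1_rho
    for (j in 2:nw) eps[, j] <- rho * eps[, j - 1L] +
        sqrt(1 - rho^2) * eps[, j]
  }
  yrs <- matrix(wt / 365.25, n, nw, byrow = TRUE)
  V <- level + params$class_drift[cls] * yrs +
    params$class_visit_sd[cls] * eps
  V <- pmax(V, params$fbg_floor)

  ## true glycemic burden from the full (attendance-free) trajectory
  burden <- switch(params$dr_driver,
    cum_load = .cum_load_matrix(wt, V, params$load_threshold),
    m_fbg = rowMeans(V),
    sd = apply(V, 1L, stats::sd))

  co <- params$dr_coef
  lp <- co[["load"]] * burden +
    co[["age"]] * (age - params$age_mean) +
    co[["male"]] * male +
    co[["smoking"]] * smoking +
    co[["drinking"]] * drinking +
    co[["hypertension"]] * htn +
    co[["dyslipidemia"]] * dys +
    co[["education_low"]] * edu_low +
    co[["income_low"]] * inc_low +
    co[["bmi"]] * (bmi - params$bmi_mean)
  b0 <- .calibrate_intercept(lp, params$dr_prevalence)
  pr_dr <- stats::plogis(b0 + lp)
  dr <- stats::rbinom(n, 1L, pr_dr)
  dr[stats::runif(n) < params$dr_missing_prob] <- NA_integer_

  ## attendance (at least one wave)
  att <- matrix(stats::rbinom(n * nw, 1L,
                              rep(params$wave_attendance, each = n)), n, nw)
  none <- rowSums(att) == 0L
  if (any(none))
    att[cbind(which(none), sample.int(nw, sum(none), replace = TRUE))] <- 1L

  keep <- which(att == 1L, arr.ind = TRUE)
  visits <- data.frame(
    participant_id = id[keep[, 1L]],
    visit_time = wt[keep[, 2L]],
    fbg = round(V[keep], 2),
    stringsAsFactors = FALSE
  )

  participants <- data.frame(
    participant_id = id,
    age = round(age, 1),
    sex = male,                       # 1 = male, 0 = female
    education = 1L - edu_low,         # 1 = high
    income = 1L - inc_low,            # 1 = high
    current_smoking = smoking,
    current_drinking = drinking,
    hypertension = htn,
    dyslipidemia = dys,
    bmi = round(bmi, 1),
    dr_status = dr,
    has_final_window_fbg = att[, nw],
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    participant_id = id,
    glycemic_class = c("normo", "pre", "diab")[cls],
    personal_level = level,
    true_burden = burden,
    linear_predictor = b0 + lp,
    dr_probability = pr_dr,
    stringsAsFactors = FALSE
  )
  attr(truth, "dr_intercept") <- b0

  structure(list(cohort = fbg_cohort(visits, participants),
                 truth = truth, params = params, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic FBG cohort (seed %d): %d participants, %d visits\n",
              x$seed, nrow(x$cohort$participants), nrow(x$cohort$visits)))
  invisible(x)
}

#' Summary of a synthetic cohort against its generating targets
#'
#' @param sc A \code{synthetic_cohort}.
#' @return A list with per-class counts, the outcome-model coefficients in
#'   force (including the calibrated intercept), and a data.frame of realised
#'   vs target marginals.
#' @export
truth_report <- function(sc) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  p <- sc$cohort$participants
  if (nrow(p) == 0L)
    return(list(class_counts = table(character(0)),
                coefficients = sc$params$dr_coef,
                marginals = data.frame()))
  v <- sc$cohort$visits
  realised <- c(
    mean_age = mean(p$age),
    female_fraction = mean(1 - p$sex),
    mean_fbg = mean(v$fbg),
    dr_prevalence = mean(p$dr_status, na.rm = TRUE),
    smoking = mean(p$current_smoking),
    drinking = mean(p$current_drinking),
    hypertension = mean(p$hypertension),
    dyslipidemia = mean(p$dyslipidemia)
  )
  target <- c(sc$params$age_mean, sc$params$female_frac, NA,
              sc$params$dr_prevalence, sc$params$prev_smoking,
              sc$params$prev_drinking, sc$params$prev_hypertension,
              sc$params$prev_dyslipidemia)
  list(
    class_counts = table(sc$truth$glycemic_class),
    coefficients = c(intercept = attr(sc$truth, "dr_intercept"),
                     sc$params$dr_coef),
    marginals = data.frame(quantity = names(realised),
                           realised = unname(realised),
                           target = target, stringsAsFactors = FALSE)
  )
}
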