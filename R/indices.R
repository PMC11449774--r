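# Visit-to-visit FBG indices.
#
# All functions operate on a single participant's time-ordered FBG series
# (times in days since first visit, values in mmol/L) except the cohort-level
# VIM calibration and compute_indices().

#' Sample standard deviation of an FBG series
#'
#' @param values Numeric vector of FBG values (mmol/L), length >= 2.
#' @return Sample (n-1 denominator) standard deviation in mmol/L.
#' @export
fbg_sd <- function(values) {
  if (length(values) < 2L)
    stop("fbg_sd() needs at least 2 values, got ", length(values))
  stats::sd(values)
}

#' Coefficient of variation of an FBG series
#'
#' CV (%) = SD / mean x 100.
#'
#' @inheritParams fbg_sd
#' @return CV in percent.
#' @export
fbg_cv <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    stop("fbg_cv() requires a positive mean FBG, got ", m)
  100 * fbg_sd(values) / m
}

#' Average real variability of an FBG series
#'
#' Mean absolute difference between consecutive (time-ordered) visit values.
#'
#' @param values Numeric vector of FBG values in visit-time order.
#' @param percent If TRUE, return ARV normalised by the series mean, in
#'   percent (the unit used for ARV in the cohort tables); otherwise mmol/L.
#' @return ARV in mmol/L (or % of mean).
#' @export
fbg_arv <- function(values, percent = FALSE) {
  n <- length(values)
  if (n < 2L)
    stop("fbg_arv() needs at least 2 values, got ", n)
  arv <- sum(abs(diff(values))) / (n - 1L)
  if (percent) 100 * arv / mean(values) else arv
}

#' Mean FBG (M-FBG)
#'
#' @inheritParams fbg_sd
#' @return Arithmetic mean of the values, mmol/L.
#' @export
fbg_mean <- function(values) {
  if (length(values) < 1L) stop("fbg_mean() needs at least 1 value")
  mean(values)
}

#' Cohort calibration of the VIM exponent
#'
#' VIM = 100 x SD / mean^beta needs a cohort-wide exponent beta, obtained as
#' the ordinary-least-squares slope of ln(SD) on ln(mean) across participants.
#' Participants with SD = 0 (constant series) have undefined ln(SD) and are
#' excluded from the fit; they are assigned VIM = 0 downstream.
#'
#' @param means Per-participant mean FBG values.
#' @param sds Per-participant FBG standard deviations (same order).
#' @return An object of class \code{vim_calibration}: list with \code{beta}
#'   (slope), \code{intercept}, and \code{n_used} (participants entering the
#'   fit).
#' @export
fit_vim_calibration <- function(means, sds) {
  stopifnot(length(means) == length(sds))
  keep <- is.finite(means) & is.finite(sds) & means > 0 & sds > 0
  if (sum(keep) < 2L)
    stop("VIM calibration needs >= 2 participants with SD > 0; got ",
         sum(keep))
  lx <- log(means[keep])
  ly <- log(sds[keep])
  if (diff(range(lx)) == 0)
    stop("VIM calibration degenerate: all participant means are equal")
  fit <- stats::lm.fit(cbind(1, lx), ly)
  structure(
    list(beta = unname(fit$coefficients[2L]),
         intercept = unname(fit$coefficients[1L]),
         n_used = sum(keep)),
    class = "vim_calibration"
  )
}

#' @export
print.vim_calibration <- function(x, ...) {
  cat(sprintf("VIM calibration: beta = %.4f (intercept %.4f, n_used = %d)\n",
              x$beta, x$intercept, x$n_used))
  invisible(x)
}

#' Variation independent of the mean
#'
#' VIM = 100 x SD / mean^beta with beta from a cohort-wide calibration, so
#' that VIM is (by construction) uncorrelated with the mean across the cohort.
#'
#' @param sd Participant FBG standard deviation (mmol/L).
#' @param mean Participant mean FBG (mmol/L).
#' @param calibration A \code{vim_calibration} object for the same cohort.
#' @return VIM in percent; 0 when sd is 0.
#' @export
fbg_vim <- function(sd, mean, calibration) {
  stopifnot(inherits(calibration, "vim_calibration"))
  if (any(!is.finite(sd)) || any(sd < 0))
    stop("fbg_vim(): sd must be finite and >= 0")
  100 * sd / mean^calibration$beta
}

#' Cumulative FBG load
#'
#' Percentage of the time-integrated FBG curve lying above a glycemic
#' threshold (default 5.6 mmol/L, the prediabetes cut-off). The series is
#' interpolated piecewise-linearly between visits; threshold crossings within
#' a segment are located analytically, so the excess area is exact for the
#' interpolant. Load = 100 x (area above threshold) / (total area under the
#' curve), both over the participant's own [first, last] visit window.
#'
#' @param times Visit times in days, strictly increasing, length >= 2.
#' @param values FBG values (mmol/L) at those times.
#' @param threshold Glycemic threshold in mmol/L (default 5.6).
#' @param method \code{"excess"} (default): numerator is the area between the
#'   curve and the threshold line where the curve exceeds it.
#'   \code{"supra"}: numerator is the full area under the curve restricted to
#'   supra-threshold intervals.
#' @return Load in percent, in [0, 100).
#' @export
cumulative_load <- function(times, values, threshold = 5.6,
                            method = c("excess", "supra")) {
  method <- match.arg(method)
  n <- length(times)
  if (n < 2L)
    stop("cumulative_load() needs at least 2 visits, got ", n)
  if (length(values) != n)
    stop("times and values differ in length")
  if (any(diff(times) <= 0))
    stop("cumulative_load(): times must be strictly increasing")
  if (!is.finite(threshold) || threshold <= 0)
    stop("cumulative_load(): threshold must be positive")
  dt <- diff(times)
  a <- values[-n]
  b <- values[-1L]
  total <- sum(dt * (a + b) / 2)
  if (total <= 0)
    stop("cumulative_load(): non-positive total area")
  excess <- sum(.segment_excess(a, b, dt, threshold, supra = method == "supra"))
  100 * excess / total
}

# Area above `thr` for linear segments from a to b over widths dt
# (vectorised over segments). With supra = TRUE returns instead the area
# under the curve itself over the sub-interval where it exceeds thr.
.segment_excess <- function(a, b, dt, thr, supra = FALSE) {
  ea <- a - thr
  eb <- b - thr
  out <- numeric(length(a))

  both_above <- ea >= 0 & eb >= 0
  both_below <- ea <= 0 & eb <= 0
  cross <- !(both_above | both_below)

  # fraction of the segment above threshold at a crossing
  # line: e(t) = ea + (eb - ea) * t/dt, zero at t* = dt * ea / (ea - eb)
  if (any(both_above))
    out[both_above] <- if (supra)
      dt[both_above] * (a[both_above] + b[both_above]) / 2
    else
      dt[both_above] * (ea[both_above] + eb[both_above]) / 2
  if (any(cross)) {
    i <- cross
    tstar <- dt[i] * ea[i] / (ea[i] - eb[i])   # crossing offset from segment start
    up_first <- ea[i] > 0                      # TRUE: starts above, ends below
    w <- ifelse(up_first, tstar, dt[i] - tstar)  # width of supra-threshold part
    e_hi <- ifelse(up_first, ea[i], eb[i])       # excess at the supra endpoint
    out[i] <- if (supra) w * (e_hi + 2 * thr) / 2 else w * e_hi / 2
  }
  out
}

#' Compute all FBG indices for a cohort
#'
#' One row per participant: baseline (first-visit) FBG, SD, CV, VIM, ARV
#' (mmol/L and % of mean), M-FBG and cumulative FBG load, plus the number of
#' visits and follow-up span. VIM uses a single cohort-wide calibration,
#' attached as attribute \code{"vim_calibration"}.
#'
#' @param cohort An \code{fbg_cohort} (ideally filtered and imputed).
#' @param threshold Glycemic threshold for cumulative load, mmol/L.
#' @param load_method Passed to \code{\link{cumulative_load}}.
#' @return A data.frame of per-participant indices with attribute
#'   \code{vim_calibration}.
#' @export
compute_indices <- function(cohort, threshold = 5.6, load_method = "excess") {
  stopifnot(inherits(cohort, "fbg_cohort"))
  v <- cohort$visits
  ids <- unique(v$participant_id)
  sp_val <- split(v$fbg, factor(v$participant_id, levels = ids))
  sp_tim <- split(v$visit_time, factor(v$participant_id, levels = ids))

  nvis <- lengths(sp_val)
  if (any(nvis < 2L))
    stop("compute_indices(): participants with < 2 visits present; ",
         "apply eligibility filters first")

  m    <- vapply(sp_val, mean, numeric(1))
  s    <- vapply(sp_val, stats::sd, numeric(1))
  arv  <- vapply(sp_val, fbg_arv, numeric(1))
  base <- vapply(sp_val, `[`, numeric(1), 1L)
  load <- mapply(function(t, x) cumulative_load(t, x, threshold, load_method),
                 sp_tim, sp_val)
  span <- vapply(sp_tim, function(t) t[length(t)] - t[1L], numeric(1))

  if (all(s == 0)) {
    # wholly constant cohort: every variability index is 0 and the VIM
    # exponent is undefined; record an empty calibration rather than fail
    cal <- structure(list(beta = NA_real_, intercept = NA_real_, n_used = 0L),
                     class = "vim_calibration")
    vim <- rep(0, length(s))
  } else {
    cal <- fit_vim_calibration(m, s)
    vim <- ifelse(s == 0, 0, fbg_vim(s, m, cal))
  }

  out <- data.frame(
    participant_id = ids,
    fbg_baseline = base,
    sd = s,
    cv = 100 * s / m,
    vim = vim,
    arv = arv,
    arv_pct = 100 * arv / m,
    m_fbg = m,
    cum_load = load,
    n_visits = as.integer(nvis),
    followup_days = span,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "vim_calibration") <- cal
  out
}

#' Scale a predictor per-unit or per-cohort-SD
#'
#' \code{per_cohort_sd} divides the values by their cohort standard deviation,
#' so a logistic coefficient on the scaled predictor is "per 1 SD increase";
#' \code{per_unit} is the identity.
#'
#' @param x Numeric predictor values across the cohort.
#' @param scheme \code{"per_unit"} or \code{"per_cohort_sd"}.
#' @return Scaled values.
#' @export
standardize_per_sd <- function(x, scheme = c("per_unit", "per_cohort_sd")) {
  scheme <- match.arg(scheme)
  if (scheme == "per_unit") return(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("standardize_per_sd(): cohort SD is zero or undefined")
  x / s
}
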