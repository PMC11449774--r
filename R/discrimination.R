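# Discrimination and reclassification statistics: AUC with DeLong variance,
# paired DeLong test, IDI, categorical NRI, information criteria, and the
# pairwise model-comparison driver.

.check_labels <- function(y) {
  if (any(is.na(y))) stop("labels contain missing values")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present")
  as.integer(y)
}

# DeLong structural components. Returns list(auc, v10 [per case],
# v01 [per control]): auc = mean(v10) = mean(v01); var(auc) =
# var(v10)/n1 + var(v01)/n0.
.delong_components <- function(risk, y) {
  x <- risk[y == 1L]
  z <- risk[y == 0L]
  # psi(x, z) = 1{x > z} + 0.5 * 1{x == z}
  M <- outer(x, z, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(M), v10 = rowMeans(M), v01 = colMeans(M))
}

#' AUC of predicted risks with DeLong standard error
#'
#' Mann-Whitney estimator (ties count one half) with standard error and
#' normal-approximation confidence interval from DeLong's structural
#' components variance.
#'
#' @param risk Predicted probabilities (or any scores), one per participant.
#' @param y Binary outcome labels (0/1), aligned to \code{risk}.
#' @param level Confidence level.
#' @return Named vector \code{c(auc, se, ci_low, ci_high)}.
#' @export
auc_delong <- function(risk, y, level = 0.95) {
  y <- .check_labels(y)
  if (length(risk) != length(y)) stop("risk and labels differ in length")
  cmp <- .delong_components(risk, y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  v <- stats::var(cmp$v10) / n1 + stats::var(cmp$v01) / n0
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(auc = cmp$auc, se = se,
    ci_low = max(0, cmp$auc - z * se), ci_high = min(1, cmp$auc + z * se))
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two risk vectors computed on the same
#' participants, using the covariance of the DeLong structural components.
#'
#' @param risk1,risk2 Aligned predicted-risk vectors (comparator, reference).
#' @param y Binary outcome labels.
#' @param level Confidence level.
#' @return Named vector \code{c(delta_auc, se, ci_low, ci_high, p)} for
#'   AUC(risk1) - AUC(risk2), with a two-sided normal p-value.
#' @export
delong_test <- function(risk1, risk2, y, level = 0.95) {
  y <- .check_labels(y)
  if (length(risk1) != length(y) || length(risk2) != length(y))
    stop("risk vectors and labels differ in length")
  c1 <- .delong_components(risk1, y)
  c2 <- .delong_components(risk2, y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  v <- (stats::var(c1$v10) + stats::var(c2$v10) -
          2 * stats::cov(c1$v10, c2$v10)) / n1 +
       (stats::var(c1$v01) + stats::var(c2$v01) -
          2 * stats::cov(c1$v01, c2$v01)) / n0
  d <- c1$auc - c2$auc
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) {
    if (d == 0) 1 else 0
  } else 2 * stats::pnorm(-abs(d / se))
  c(delta_auc = d, se = se, ci_low = d - z * se, ci_high = d + z * se, p = p)
}

#' Integrated discrimination improvement
#'
#' IDI = [mean(new risk | case) - mean(old risk | case)] -
#' [mean(new risk | control) - mean(old risk | control)]; the standard error
#' combines the standard errors of the paired risk differences within cases
#' and within controls.
#'
#' @param risk_new,risk_old Aligned predicted-risk vectors.
#' @param y Binary outcome labels.
#' @param level Confidence level.
#' @param boot Number of bootstrap resamples for a percentile CI (0 =
#'   asymptotic CI only).
#' @param boot_seed Seed for the bootstrap.
#' @return Named vector \code{c(idi, se, ci_low, ci_high, p)} (bootstrap CI
#'   replaces the asymptotic one when \code{boot > 0}).
#' @export
compute_idi <- function(risk_new, risk_old, y, level = 0.95, boot = 0L,
                        boot_seed = 1L) {
  y <- .check_labels(y)
  if (length(risk_new) != length(y) || length(risk_old) != length(y))
    stop("risk vectors and labels differ in length")
  d <- risk_new - risk_old
  d1 <- d[y == 1L]; d0 <- d[y == 0L]
  idi <- mean(d1) - mean(d0)
  se <- sqrt(stats::var(d1) / length(d1) + stats::var(d0) / length(d0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) {
    if (idi == 0) 1 else 0
  } else 2 * stats::pnorm(-abs(idi / se))
  lo <- idi - z * se; hi <- idi + z * se
  if (boot > 0L) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(as.integer(boot_seed))
    i1 <- which(y == 1L); i0 <- which(y == 0L)
    stat <- vapply(seq_len(boot), function(b) {
      s1 <- sample(i1, replace = TRUE); s0 <- sample(i0, replace = TRUE)
      mean(d[s1]) - mean(d[s0])
    }, numeric(1))
    qs <- stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    lo <- qs[1L]; hi <- qs[2L]
  }
  c(idi = idi, se = se, ci_low = lo, ci_high = hi, p = p)
}

#' Categorical net reclassification index
#'
#' Participants are assigned to risk categories by cutting both risk vectors
#' at the same thresholds. NRI = [P(up | case) - P(down | case)] +
#' [P(down | control) - P(up | control)], with the usual asymptotic standard
#' error.
#'
#' @param risk_new,risk_old Aligned predicted-risk vectors.
#' @param y Binary outcome labels.
#' @param cuts Strictly increasing category boundaries in (0, 1); the
#'   default \code{c(0.05, 0.15)} defines the conventional three categories.
#' @param level Confidence level.
#' @return List with \code{estimate} (named vector \code{nri, se, ci_low,
#'   ci_high, p}, plus the case and control components) and
#'   \code{reclassification} (old-by-new cross-tabulations for cases and
#'   controls).
#' @export
nri_categorical <- function(risk_new, risk_old, y, cuts = c(0.05, 0.15),
                            level = 0.95) {
  y <- .check_labels(y)
  if (length(risk_new) != length(y) || length(risk_old) != length(y))
    stop("risk vectors and labels differ in length")
  if (length(cuts) < 1L) stop("at least one category cut is required")
  if (any(diff(cuts) <= 0) || any(cuts <= 0) || any(cuts >= 1))
    stop("cuts must be strictly increasing and inside (0, 1)")
  brk <- c(-Inf, cuts, Inf)
  cat_new <- cut(risk_new, brk, labels = FALSE)
  cat_old <- cut(risk_old, brk, labels = FALSE)
  ncat <- length(cuts) + 1L
  lev <- factor(seq_len(ncat),
                labels = sprintf("[%s,%s)", c(0, cuts), c(cuts, 1)))

  tab <- function(sel) table(
    old = factor(cat_old[sel], levels = seq_len(ncat), labels = levels(lev)),
    new = factor(cat_new[sel], levels = seq_len(ncat), labels = levels(lev)))
  case <- y == 1L; ctrl <- y == 0L
  n1 <- sum(case); n0 <- sum(ctrl)

  up1 <- mean(cat_new[case] > cat_old[case])
  dn1 <- mean(cat_new[case] < cat_old[case])
  up0 <- mean(cat_new[ctrl] > cat_old[ctrl])
  dn0 <- mean(cat_new[ctrl] < cat_old[ctrl])
  nri <- (up1 - dn1) + (dn0 - up0)
  se <- sqrt((up1 + dn1 - (up1 - dn1)^2) / n1 +
             (up0 + dn0 - (dn0 - up0)^2) / n0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) {
    if (nri == 0) 1 else 0
  } else 2 * stats::pnorm(-abs(nri / se))
  list(
    estimate = c(nri = nri, se = se, ci_low = nri - z * se,
                 ci_high = nri + z * se, p = p,
                 nri_cases = up1 - dn1, nri_controls = dn0 - up0),
    reclassification = list(cases = tab(case), controls = tab(ctrl))
  )
}

#' Akaike and Bayesian information criteria of a fitted model
#'
#' AIC = -2 logLik + 2k; BIC = -2 logLik + k ln(n), with k the number of
#' estimated coefficients (intercept included).
#'
#' @param model A \code{dr_model} (or any list with \code{log_likelihood},
#'   \code{k}, \code{n}).
#' @return Named vector \code{c(aic, bic)}.
#' @export
information_criteria <- function(model) {
  c(aic = -2 * model$log_likelihood + 2 * model$k,
    bic = -2 * model$log_likelihood + model$k * log(model$n))
}

#' Compare fitted risk models against a reference model
#'
#' For every non-reference model: change in AUC with the paired DeLong test,
#' IDI, categorical NRI, and AIC/BIC differences (comparator minus
#' reference). All fits must be on the same participants in the same order.
#'
#' @param fits Named list of \code{dr_model} objects.
#' @param reference Name (or index) of the reference model in \code{fits}.
#' @param cuts NRI category boundaries.
#' @param idi_boot Bootstrap resamples for the IDI CI (0 = asymptotic).
#' @param seed Seed used for any bootstrap.
#' @return A data.frame, one row per comparator model, with AUC, delta-AUC
#'   (CI, p), IDI (CI, p), NRI (CI, p), delta-AIC and delta-BIC columns; the
#'   reference row appears first with zero deltas.
#' @export
compare_models <- function(fits, reference = 1L, cuts = c(0.05, 0.15),
                           idi_boot = 0L, seed = 1L) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  if (is.character(reference)) {
    if (!reference %in% names(fits))
      stop("reference model '", reference, "' not in fits")
    ref_i <- match(reference, names(fits))
  } else {
    if (reference < 1L || reference > length(fits))
      stop("reference index out of range")
    ref_i <- as.integer(reference)
  }
  ref <- fits[[ref_i]]
  y <- ref$fit$y
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (any(ns != ref$n))
    stop("all fits must be on identical participants")
  ic_ref <- information_criteria(ref)
  labels <- names(fits) %||% vapply(fits, function(f) f$label, character(1))

  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    a <- auc_delong(f$predicted_risks, y)
    if (i == ref_i) {
      data.frame(model = labels[i], reference = TRUE,
                 auc = a[["auc"]], auc_ci_low = a[["ci_low"]],
                 auc_ci_high = a[["ci_high"]],
                 delta_auc = 0, delta_auc_ci_low = 0, delta_auc_ci_high = 0,
                 delta_auc_p = 1,
                 idi = 0, idi_ci_low = 0, idi_ci_high = 0, idi_p = 1,
                 nri = 0, nri_ci_low = 0, nri_ci_high = 0, nri_p = 1,
                 aic = ic_ref[["aic"]], bic = ic_ref[["bic"]],
                 delta_aic = 0, delta_bic = 0, stringsAsFactors = FALSE)
    } else {
      dl <- delong_test(f$predicted_risks, ref$predicted_risks, y)
      idi <- compute_idi(f$predicted_risks, ref$predicted_risks, y,
                         boot = idi_boot, boot_seed = seed + i)
      nri <- nri_categorical(f$predicted_risks, ref$predicted_risks, y,
                             cuts)$estimate
      ic <- information_criteria(f)
      data.frame(model = labels[i], reference = FALSE,
                 auc = a[["auc"]], auc_ci_low = a[["ci_low"]],
                 auc_ci_high = a[["ci_high"]],
                 delta_auc = dl[["delta_auc"]],
                 delta_auc_ci_low = dl[["ci_low"]],
                 delta_auc_ci_high = dl[["ci_high"]],
                 delta_auc_p = dl[["p"]],
                 idi = idi[["idi"]], idi_ci_low = idi[["ci_low"]],
                 idi_ci_high = idi[["ci_high"]], idi_p = idi[["p"]],
                 nri = nri[["nri"]], nri_ci_low = nri[["ci_low"]],
                 nri_ci_high = nri[["ci_high"]], nri_p = nri[["p"]],
                 aic = ic[["aic"]], bic = ic[["bic"]],
                 delta_aic = ic[["aic"]] - ic_ref[["aic"]],
                 delta_bic = ic[["bic"]] - ic_ref[["bic"]],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, c(rows[ref_i], rows[-ref_i]))
  rownames(out) <- NULL
  out
}
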