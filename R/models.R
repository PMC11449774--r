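# Covariate-adjusted logistic models of DR on the FBG indices.

.classical_terms <- c("age", "sex", "bmi", "education", "income",
                      "current_smoking", "current_drinking",
                      "hypertension", "dyslipidemia")
.index_terms <- c("fbg_baseline", "sd", "cv", "vim", "arv_pct",
                  "m_fbg", "cum_load")

# Table-style labels for the seven indices
.index_labels <- c(fbg_baseline = "FBG", sd = "SD", cv = "CV", vim = "VIM",
                   arv_pct = "ARV", m_fbg = "M-FBG",
                   cum_load = "cumulative FBG load")

#' Default per-index scaling for association models
#'
#' FBG, SD and M-FBG enter per unit (mmol/L); CV, VIM, ARV and cumulative
#' FBG load per 1 cohort-SD increase.
#'
#' @return Named character vector mapping index column to scaling scheme.
#' @export
default_scaling <- function() {
  c(fbg_baseline = "per_unit", sd = "per_unit", m_fbg = "per_unit",
    cv = "per_cohort_sd", vim = "per_cohort_sd", arv_pct = "per_cohort_sd",
    cum_load = "per_cohort_sd")
}

#' Merge participants and indices into an analysis dataset
#'
#' Applies the per-index scaling so fitted coefficients carry the intended
#' "per unit" / "per 1 SD increase" interpretation.
#'
#' @param cohort A filtered, imputed \code{fbg_cohort}.
#' @param indices The index table from \code{\link{compute_indices}}.
#' @param scaling Named scaling map (see \code{\link{default_scaling}}).
#' @return A data.frame with one row per analysed participant.
#' @export
analysis_data <- function(cohort, indices, scaling = default_scaling()) {
  stopifnot(inherits(cohort, "fbg_cohort"))
  d <- merge(cohort$participants, indices, by = "participant_id",
             sort = TRUE)
  for (term in intersect(names(scaling), names(d)))
    d[[term]] <- standardize_per_sd(d[[term]], scaling[[term]])
  attr(d, "scaling") <- scaling
  d
}

#' Fit a logistic DR model
#'
#' Binary maximum-likelihood logistic regression of DR status on the given
#' predictor terms (the analysed outcome has two levels, so a two-category
#' multinomial fit is identical). Perfect separation and non-convergence are
#' raised as errors with the offending term named.
#'
#' @param data Analysis data.frame from \code{\link{analysis_data}} (or any
#'   data.frame with the outcome and terms).
#' @param predictors Character vector of predictor column names.
#' @param outcome Name of the binary outcome column (default
#'   \code{"dr_status"}).
#' @param label Optional model label.
#' @return An object of class \code{dr_model}: list with the \code{glm} fit,
#'   \code{coefficients}, \code{vcov}, \code{log_likelihood}, \code{n},
#'   \code{k}, \code{predicted_risks}, \code{converged}, \code{label}.
#' @export
fit_dr_model <- function(data, predictors, outcome = "dr_status",
                         label = NULL) {
  if (anyDuplicated(predictors))
    stop("duplicate predictor terms: ",
         paste(unique(predictors[duplicated(predictors)]), collapse = ", "))
  if (outcome %in% predictors)
    stop("outcome '", outcome, "' cannot also be a predictor")
  miss <- setdiff(c(outcome, predictors), names(data))
  if (length(miss))
    stop("terms not found in data: ", paste(miss, collapse = ", "))
  y <- data[[outcome]]
  if (any(is.na(y)))
    stop("outcome contains missing values; filter the cohort first")
  if (length(unique(y)) < 2L)
    stop("outcome has a single level; cannot fit")

  fml <- stats::as.formula(paste(
    outcome, "~",
    if (length(predictors)) paste(predictors, collapse = " + ") else "1"))
  warned <- character(0)
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = data,
               control = stats::glm.control(maxit = 50L)),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  mu <- stats::fitted(fit)
  degenerate <- any(mu < 1e-10) || any(mu > 1 - 1e-10)
  sep <- (any(grepl("fitted probabilities numerically 0 or 1", warned)) ||
            degenerate || !fit$converged) &&
    length(cf) > 1L && any(abs(cf[-1L]) > 10)
  if (sep) {
    worst <- names(which.max(abs(cf[-1L])))
    stop("(quasi-)perfect separation detected; largest coefficient on term '",
         worst, "'")
  }
  if (!fit$converged)
    stop("logistic fit did not converge after ", fit$control$maxit,
         " iterations; deviance = ", format(fit$deviance))
  pr <- as.numeric(stats::fitted(fit))
  structure(
    list(fit = fit,
         predictors = predictors,
         outcome = outcome,
         coefficients = stats::coef(fit),
         vcov = stats::vcov(fit),
         log_likelihood = as.numeric(stats::logLik(fit)),
         n = length(y),
         k = length(stats::coef(fit)),
         predicted_risks = pr,
         converged = fit$converged,
         label = label %||% paste(predictors, collapse = " + ")),
    class = "dr_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dr_model <- function(x, ...) {
  cat("Logistic DR model:", x$label, "\n")
  cat(sprintf("  n = %d, k = %d, logLik = %.3f\n",
              x$n, x$k, x$log_likelihood))
  invisible(x)
}

#' Odds ratio with Wald 95\% confidence interval for a model term
#'
#' @param model A \code{dr_model}.
#' @param term Coefficient name.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector \code{c(or, ci_low, ci_high, p)}.
#' @export
extract_or <- function(model, term, level = 0.95) {
  stopifnot(inherits(model, "dr_model"))
  if (!term %in% names(model$coefficients))
    stop("term '", term, "' not in model (has: ",
         paste(names(model$coefficients), collapse = ", "), ")")
  b <- model$coefficients[[term]]
  se <- sqrt(model$vcov[term, term])
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se),
    p = 2 * stats::pnorm(-abs(b / se)))
}

#' The model grid of the risk-prediction comparison
#'
#' Eighteen model specifications in table order: classical risk factors
#' alone; classical + each of the seven single indices; and the ten listed
#' two/three-index combinations (each including FBG and/or cumulative load).
#'
#' @param indices Index columns available (default the seven standard ones);
#'   combinations whose members are not all available are dropped.
#' @param classical Covariate set used in every model.
#' @return Named list of character vectors of predictor terms.
#' @export
build_model_grid <- function(indices = .index_terms,
                             classical = .classical_terms) {
  combos <- list(
    c("fbg_baseline", "sd"),
    c("fbg_baseline", "cv"),
    c("fbg_baseline", "cum_load"),
    c("sd", "cum_load"),
    c("cv", "cum_load"),
    c("arv_pct", "cum_load"),
    c("fbg_baseline", "sd", "cum_load"),
    c("fbg_baseline", "cv", "cum_load"),
    c("fbg_baseline", "vim", "cum_load"),
    c("fbg_baseline", "arv_pct", "cum_load")
  )
  specs <- c(list(character(0)),
             lapply(intersect(.index_terms, indices), identity),
             Filter(function(cc) all(cc %in% indices), combos))
  terms <- lapply(specs, function(s) c(classical, s))
  lab <- vapply(specs, function(s) {
    if (!length(s)) "Classical risk factors"
    else paste("Classical risk factors +",
               paste(.index_labels[s], collapse = " + "))
  }, character(1))
  names(terms) <- lab
  terms
}
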