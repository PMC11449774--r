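# Longitudinal cohort container, readers, comorbidity derivation,
# eligibility filters and single-value imputation.

.participant_required <- c("participant_id", "age", "sex", "bmi",
                           "dr_status", "has_final_window_fbg")
.participant_known <- c(
  .participant_required,
  "education", "income", "current_smoking", "current_drinking",
  "sbp", "dbp", "ldl_c", "hdl_c", "tc", "tg",
  "self_report_hypertension", "antihypertensive_use",
  "self_report_dyslipidemia", "lipid_lowering_use",
  "hypertension", "dyslipidemia"
)

#' Construct a cohort from visit and participant tables
#'
#' @param visits data.frame with columns \code{participant_id},
#'   \code{visit_time} (days since baseline, >= 0) and \code{fbg} (mmol/L, > 0).
#' @param participants data.frame with one row per participant; see
#'   \code{\link{read_cohort}} for the column contract.
#' @return An object of class \code{fbg_cohort}: a list with elements
#'   \code{visits} (time-sorted within participant) and \code{participants}.
#' @export
fbg_cohort <- function(visits, participants) {
  stopifnot(is.data.frame(visits), is.data.frame(participants))
  need_v <- c("participant_id", "visit_time", "fbg")
  miss <- setdiff(need_v, names(visits))
  if (length(miss))
    stop("visits table missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(.participant_required, names(participants))
  if (length(miss))
    stop("participants table missing column(s): ", paste(miss, collapse = ", "))

  bad <- which(!is.finite(visits$fbg) | visits$fbg <= 0)
  if (length(bad))
    stop("non-positive or missing fbg in visits row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(!is.finite(visits$visit_time) | visits$visit_time < 0)
  if (length(bad))
    stop("negative or missing visit_time in visits row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  key <- paste(visits$participant_id, visits$visit_time, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad))
    stop("duplicate (participant_id, visit_time) in visits row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (anyDuplicated(participants$participant_id))
    stop("duplicate participant_id in participants table")
  unknown <- setdiff(unique(visits$participant_id),
                     participants$participant_id)
  if (length(unknown))
    stop("visits reference unknown participant id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  bad <- which(!is.finite(participants$age) | participants$age <= 0)
  if (length(bad))
    stop("non-positive age in participants row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if ("bmi" %in% names(participants)) {
    bad <- which(!is.na(participants$bmi) & participants$bmi <= 0)
    if (length(bad))
      stop("non-positive bmi in participants row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }

  visits <- visits[order(visits$participant_id, visits$visit_time), ,
                   drop = FALSE]
  rownames(visits) <- NULL
  rownames(participants) <- NULL
  structure(list(visits = visits, participants = participants),
            class = "fbg_cohort")
}

#' @export
print.fbg_cohort <- function(x, ...) {
  cat(sprintf("FBG cohort: %d participants, %d visits\n",
              nrow(x$participants), nrow(x$visits)))
  fl <- attr(x, "filter_log")
  if (!is.null(fl)) cat("  (eligibility-filtered; see filter_log())\n")
  invisible(x)
}

#' Read a cohort from delimited text files
#'
#' The visits file must have columns \code{participant_id},
#' \code{visit_time_days}, \code{fbg_mmol_l}. The participants file has one
#' row per participant with at least \code{participant_id}, \code{age},
#' \code{sex} (\code{female}/\code{male} or 0/1), \code{bmi},
#' \code{dr_status}, \code{has_final_window_fbg}; optional columns are
#' \code{education} (\code{low}/\code{high}), \code{income},
#' \code{current_smoking}, \code{current_drinking}, blood pressure
#' (\code{sbp}, \code{dbp}), lipids (\code{ldl_c}, \code{hdl_c}, \code{tc},
#' \code{tg}), self-report/medication flags and pre-derived
#' \code{hypertension}/\code{dyslipidemia}. Missing values are empty fields
#' or NA.
#'
#' @param visits_path,participants_path Paths to delimited text files
#'   (delimiter sniffed from the header among tab, comma, semicolon).
#' @return An \code{fbg_cohort}.
#' @export
read_cohort <- function(visits_path, participants_path) {
  visits <- .read_delim(visits_path)
  participants <- .read_delim(participants_path)

  ren <- c(visit_time_days = "visit_time", fbg_mmol_l = "fbg")
  for (old in names(ren))
    names(visits)[names(visits) == old] <- ren[[old]]

  for (col in c("visit_time", "fbg"))
    if (col %in% names(visits)) visits[[col]] <- .as_num(visits[[col]], col,
                                                         visits_path)
  if ("sex" %in% names(participants) && is.character(participants$sex))
    participants$sex <- ifelse(participants$sex == "", NA,
                               ifelse(participants$sex == "male", 1L, 0L))
  if ("education" %in% names(participants) &&
      is.character(participants$education))
    participants$education <- ifelse(participants$education == "", NA,
                                     ifelse(participants$education == "low",
                                            0L, 1L))
  if ("income" %in% names(participants) && is.character(participants$income))
    participants$income <- ifelse(participants$income == "", NA,
                                  ifelse(participants$income == "low", 0L, 1L))
  fbg_cohort(visits, participants)
}

.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
}

.as_num <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("unparseable ", col, " in ", path, ", row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  out
}

#' Derive hypertension and dyslipidemia flags
#'
#' Hypertension: SBP >= 140 mmHg, or DBP >= 90 mmHg, or self-reported
#' history, or current antihypertensive use. Dyslipidemia: LDL-C >= 3.37, or
#' HDL-C < 1.04, or TC >= 5.18, or TG >= 1.7 mmol/L, or self-reported
#' history, or lipid-lowering medication. A pre-supplied (non-missing)
#' \code{hypertension}/\code{dyslipidemia} flag is respected and never
#' overwritten. If every input to a flag is missing the flag is left missing
#' for later imputation.
#'
#' @param participants A participants data.frame (or an \code{fbg_cohort},
#'   in which case the flags are derived in place).
#' @return Same type as the input, with \code{hypertension} and
#'   \code{dyslipidemia} columns filled in.
#' @export
derive_comorbidity_flags <- function(participants) {
  if (inherits(participants, "fbg_cohort")) {
    participants$participants <-
      derive_comorbidity_flags(participants$participants)
    return(participants)
  }
  p <- participants
  n <- nrow(p)
  get <- function(col) if (col %in% names(p)) p[[col]] else rep(NA_real_, n)

  htn_inputs <- cbind(get("sbp") >= 140, get("dbp") >= 90,
                      get("self_report_hypertension") == 1,
                      get("antihypertensive_use") == 1)
  dys_inputs <- cbind(get("ldl_c") >= 3.37, get("hdl_c") < 1.04,
                      get("tc") >= 5.18, get("tg") >= 1.7,
                      get("self_report_dyslipidemia") == 1,
                      get("lipid_lowering_use") == 1)

  derive <- function(inputs) {
    any_true <- apply(inputs, 1L, function(r) any(r %in% TRUE))
    all_na <- apply(inputs, 1L, function(r) all(is.na(r)))
    ifelse(all_na, NA_integer_, as.integer(any_true))
  }
  htn <- derive(htn_inputs)
  dys <- derive(dys_inputs)

  pre_htn <- get("hypertension")
  pre_dys <- get("dyslipidemia")
  p$hypertension <- ifelse(!is.na(pre_htn), pre_htn, htn)
  p$dyslipidemia <- ifelse(!is.na(pre_dys), pre_dys, dys)
  p
}

#' Apply the eligibility filters
#'
#' Retains, in order: participants with at least 3 FBG visits (the boundary
#' is inclusive); then those with an FBG test in the final screening window
#' (\code{has_final_window_fbg}); then those with a gradable, non-missing DR
#' outcome. The exclusion count per criterion, in application order, is
#' attached as attribute \code{"filter_log"} (see \code{\link{filter_log}}).
#'
#' @param cohort An \code{fbg_cohort}.
#' @param min_visits Minimum number of FBG visits required (default 3).
#' @return The filtered \code{fbg_cohort} with a \code{filter_log} attribute.
#' @export
apply_eligibility_filters <- function(cohort, min_visits = 3L) {
  stopifnot(inherits(cohort, "fbg_cohort"))
  p <- cohort$participants
  v <- cohort$visits

  nvis <- table(factor(v$participant_id, levels = p$participant_id))
  keep1 <- as.vector(nvis) >= min_visits
  n1 <- sum(!keep1)

  keep2 <- keep1 & !is.na(p$has_final_window_fbg) & p$has_final_window_fbg == 1
  n2 <- sum(keep1) - sum(keep2)

  keep3 <- keep2 & !is.na(p$dr_status)
  n3 <- sum(keep2) - sum(keep3)

  log <- data.frame(
    criterion = c(sprintf("fewer_than_%d_fbg_tests", min_visits),
                  "no_final_window_fbg", "missing_dr_status"),
    n_excluded = c(n1, n2, n3),
    n_remaining = c(sum(keep1), sum(keep2), sum(keep3)),
    stringsAsFactors = FALSE
  )

  out <- fbg_cohort(
    v[v$participant_id %in% p$participant_id[keep3], , drop = FALSE],
    p[keep3, , drop = FALSE]
  )
  attr(out, "filter_log") <- log
  attr(out, "imputation_report") <- attr(cohort, "imputation_report")
  out
}

#' Eligibility filter log of a cohort
#' @param cohort A cohort returned by \code{\link{apply_eligibility_filters}}.
#' @return data.frame with columns criterion, n_excluded, n_remaining.
#' @export
filter_log <- function(cohort) attr(cohort, "filter_log")

#' Impute missing covariates by cohort mean / median
#'
#' Continuous covariates (age, BMI, blood pressure, lipids) have missing
#' values replaced by the cohort mean of the observed values; binary/ordinal
#' covariates (sex, education, income, smoking, drinking, hypertension,
#' dyslipidemia) by the cohort median of the 0/1 coding, which for binary
#' variables is the mode; an exact tie (median 0.5) rounds down to 0. A per
#' variable count of imputed values is attached as attribute
#' \code{"imputation_report"}.
#'
#' @param cohort An \code{fbg_cohort} (normally already filtered).
#' @return The cohort with covariates completed.
#' @export
impute_missing_covariates <- function(cohort) {
  stopifnot(inherits(cohort, "fbg_cohort"))
  p <- cohort$participants
  continuous <- intersect(c("age", "bmi", "sbp", "dbp",
                            "ldl_c", "hdl_c", "tc", "tg"), names(p))
  categorical <- intersect(c("sex", "education", "income", "current_smoking",
                             "current_drinking", "hypertension",
                             "dyslipidemia"), names(p))
  rep_var <- character(0); rep_n <- integer(0); rep_val <- numeric(0)
  for (col in c(continuous, categorical)) {
    x <- p[[col]]
    nmiss <- sum(is.na(x))
    if (nmiss == 0L) next
    if (nmiss == length(x))
      stop("covariate '", col, "' is missing for every participant")
    fill <- if (col %in% continuous) mean(x, na.rm = TRUE)
            else floor(stats::median(x, na.rm = TRUE))  # tie rounds down
    x[is.na(x)] <- fill
    p[[col]] <- x
    rep_var <- c(rep_var, col); rep_n <- c(rep_n, nmiss)
    rep_val <- c(rep_val, fill)
  }
  out <- fbg_cohort(cohort$visits, p)
  attr(out, "filter_log") <- attr(cohort, "filter_log")
  attr(out, "imputation_report") <- data.frame(
    variable = rep_var, n_imputed = rep_n, imputed_value = rep_val,
    stringsAsFactors = FALSE)
  out
}

#' Imputation report of a cohort
#' @param cohort A cohort returned by \code{\link{impute_missing_covariates}}.
#' @return data.frame with columns variable, n_imputed, imputed_value (empty
#'   if no imputation was performed).
#' @export
imputation_report <- function(cohort) {
  rep <- attr(cohort, "imputation_report")
  if (is.null(rep))
    rep <- data.frame(variable = character(0), n_imputed = integer(0),
                      imputed_value = numeric(0), stringsAsFactors = FALSE)
  rep
}
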