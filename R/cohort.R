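# Cohort-level statistics: descriptive summaries, diagnostic performance of
# p16 scores against the multi-disciplinary diagnosis, HRCT visual fibrosis
# scoring and ROC-based cutoff derivation.

COHORT_DIAGNOSES <- c("IPF", "NSIP", "unclassifiable", "chronic_HP",
                      "smoking_related")
COHORT_NUMERIC <- c("density", "age", "bmi", "pack_years", "fvc_pct",
                    "tlc_pct", "dlco_pct", "hrct_score_pct", "followup_months")
COHORT_CATEGORICAL <- c("diagnosis", "p16_class", "sex", "hrct_pattern",
                        "treatment", "status")

#' Read a cohort table
#'
#' One row per subject with the patient-record fields (diagnosis, density,
#' demographics, pulmonary function, HRCT, treatment, follow-up, status).
#' Empty cells become `NA`.
#'
#' @param path TSV file path.
#' @return Data frame.
#' @export
read_cohort <- function(path) {
  cohort <- read_tsv(path, na.strings = c("NA", ""))
  required <- c("patient_id", "diagnosis", "density", "followup_months", "status")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    stop(sprintf("cohort table lacks required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  cohort
}

binom_ci <- function(x, n, conf.level = 0.95) {
  # Clopper-Pearson exact interval
  as.numeric(stats::binom.test(x, n, conf.level = conf.level)$conf.int)
}

#' Diagnostic performance of a binary predictor
#'
#' Cross-tabulates a predictor rule against a truth rule over the cohort and
#' reports sensitivity and specificity with exact (Clopper-Pearson) binomial
#' 95% confidence intervals.
#'
#' @param cohort Cohort data frame.
#' @param predictor Function of the cohort returning a logical vector, or a
#'   logical vector.
#' @param truth Same convention as `predictor`; `TRUE` marks the target
#'   diagnosis.
#' @param conf.level Confidence level for the exact intervals.
#' @return List with `counts` (tp, fp, tn, fn), `sensitivity`, `specificity`
#'   (proportions), and their confidence intervals.
#' @export
diagnostic_performance <- function(cohort, predictor, truth, conf.level = 0.95) {
  pred <- if (is.function(predictor)) predictor(cohort) else predictor
  tru <- if (is.function(truth)) truth(cohort) else truth
  stopifnot(is.logical(pred), is.logical(tru), length(pred) == length(tru))
  if (anyNA(pred) || anyNA(tru)) {
    stop("predictor and truth must be defined for every subject", call. = FALSE)
  }
  tp <- sum(pred & tru); fn <- sum(!pred & tru)
  tn <- sum(!pred & !tru); fp <- sum(pred & !tru)
  if (tp + fn == 0) stop("sensitivity undefined: no positive truth cases", call. = FALSE)
  if (tn + fp == 0) stop("specificity undefined: no negative truth cases", call. = FALSE)
  structure(list(
    counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    sensitivity_ci = binom_ci(tp, tp + fn, conf.level),
    specificity_ci = binom_ci(tn, tn + fp, conf.level),
    conf.level = conf.level
  ), class = "diagnostic_performance")
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  cat(sprintf("sensitivity %.1f%% (%.0f%% CI %.1f-%.1f), specificity %.1f%% (CI %.1f-%.1f)\n",
              100 * x$sensitivity, 100 * x$conf.level,
              100 * x$sensitivity_ci[1], 100 * x$sensitivity_ci[2],
              100 * x$specificity, 100 * x$specificity_ci[1],
              100 * x$specificity_ci[2]))
  print(x$counts)
  invisible(x)
}

#' HRCT visual fibrosis score
#'
#' Extent-of-fibrosis grades (0-4, for 0-25/25-50/50-75/75-100% involvement)
#' are recorded at predefined scan levels in each hemithorax; the overall
#' score is the grade sum as a percentage of the maximum (8 x number of
#' scans).
#'
#' @param grades Integer vector of grades, length `2 * n_scans`.
#' @param n_scans Number of scan levels (default `length(grades) / 2`).
#' @return Score in percent, in `[0, 100]`.
#' @export
hrct_score <- function(grades, n_scans = length(grades) / 2) {
  if (any(!grades %in% 0:4)) {
    stop("HRCT grades must be integers between 0 and 4", call. = FALSE)
  }
  if (n_scans != round(n_scans) || length(grades) != 2 * n_scans) {
    stop("expected one grade per scan level per hemithorax (2 x n_scans)",
         call. = FALSE)
  }
  100 * sum(grades) / (8 * n_scans)
}

#' ROC analysis with accuracy-maximizing cutoff
#'
#' Thresholds are midpoints between consecutive distinct observed values plus
#' -Inf/+Inf sentinels; positivity is `value > threshold`. The AUC uses the
#' Mann-Whitney rank identity (ties scored 1/2). The best cutoff maximizes
#' accuracy in the sum-of-sensitivity-and-specificity sense, ties broken
#' toward the smallest (most inclusive) threshold.
#'
#' @param values Numeric predictor (e.g. foci density per 100 mm^2).
#' @param events Logical outcome indicator, both classes present.
#' @return A `roc_result` list: `thresholds`, `sensitivity`, `specificity`,
#'   `auc`, `best_cutoff`, `best_accuracy`.
#' @export
roc_curve <- function(values, events) {
  stopifnot(is.numeric(values), length(values) == length(events))
  events <- as.logical(events)
  if (anyNA(values) || anyNA(events) || any(!is.finite(values))) {
    stop("values must be finite and events defined for every subject", call. = FALSE)
  }
  n1 <- sum(events); n0 <- sum(!events)
  if (n1 == 0 || n0 == 0) {
    stop("degenerate ROC: both event classes must be present", call. = FALSE)
  }
  v <- sort(unique(values))
  thresholds <- c(-Inf, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2, Inf)
  sens <- vapply(thresholds, function(t) sum(values > t & events) / n1, numeric(1))
  spec <- vapply(thresholds, function(t) sum(values <= t & !events) / n0, numeric(1))
  r <- rank(values)  # midranks handle ties (1/2 credit per tied pair)
  auc <- (sum(r[events]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  acc <- sens + spec
  best <- which(acc == max(acc))[1]  # smallest threshold among ties
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc,
                 best_cutoff = thresholds[best],
                 best_accuracy = acc[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d thresholds: AUC %.3f; best cutoff %.3g (sens %.1f%%, spec %.1f%%)\n",
              length(x$thresholds), x$auc, x$best_cutoff,
              100 * x$sensitivity[match(x$best_cutoff, x$thresholds)],
              100 * x$specificity[match(x$best_cutoff, x$thresholds)]))
  invisible(x)
}

#' Descriptive cohort summary
#'
#' Mean +/- SD for continuous fields, n (%) for categorical fields (missing
#' values excluded pairwise with the non-missing count reported), plus
#' outcome incidences: combined death-or-transplant and mortality, rounded to
#' the nearest integer percent.
#'
#' @param cohort Cohort data frame.
#' @return List with `continuous` and `categorical` tables and `outcomes`.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  num_fields <- intersect(COHORT_NUMERIC, names(cohort))
  continuous <- do.call(rbind, lapply(num_fields, function(f) {
    x <- cohort[[f]][!is.na(cohort[[f]])]
    data.frame(field = f, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else 0,
               stringsAsFactors = FALSE)
  }))
  cat_fields <- intersect(COHORT_CATEGORICAL, names(cohort))
  categorical <- do.call(rbind, lapply(cat_fields, function(f) {
    x <- cohort[[f]][!is.na(cohort[[f]])]
    tab <- table(x)
    data.frame(field = f, level = names(tab), n = as.integer(tab),
               pct = round(100 * as.integer(tab) / length(x)),
               stringsAsFactors = FALSE)
  }))
  outcomes <- NULL
  if ("status" %in% names(cohort)) {
    status <- cohort$status[!is.na(cohort$status)]
    n <- length(status)
    outcomes <- list(
      n = n,
      n_alive = sum(status == "alive"),
      n_transplanted = sum(status == "transplanted"),
      n_died = sum(status == "died"),
      combined_death_or_ltx_pct = round(100 * sum(status %in% c("died", "transplanted")) / n),
      mortality_pct = round(100 * sum(status == "died") / n)
    )
  }
  list(continuous = continuous, categorical = categorical, outcomes = outcomes)
}
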