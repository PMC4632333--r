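#' Cohort-level statistics and classifier evaluation
#'
#' Group comparisons of fluctuation ratios (and of log temporal fluctuations
#' or peak frequencies) between PD and ET cohorts: pooled-variance two-sample
#' t-tests, separation distances, a sweep over delay-unit pairs and axes, and
#' confusion-matrix performance metrics with PD as the positive case.
#'
#' @name cohort
NULL

#' Default delay-unit grid for the sweep
#'
#' The eight (d1, d2) pairs used for the published delay-unit sweep.
#' @return List of [delay_pair()] objects.
#' @export
default_lag_grid <- function() {
  pairs <- list(c(5, 10), c(5, 20), c(10, 20), c(10, 30),
                c(15, 30), c(15, 40), c(20, 30), c(20, 40))
  lapply(pairs, function(p) delay_pair(p[1], p[2]))
}

#' Confusion counts
#'
#' @param TP,TN,FP,FN Nonnegative integer counts; PD is the positive case.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be nonnegative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' Count confusion cells from true and predicted labels
#'
#' @param truth,predicted Character vectors of `"PD"` / `"ET"` labels
#'   (predictions may also be `"indeterminate"`, which counts as an error
#'   against either truth).
#' @return A [confusion_counts()] object.
#' @export
count_confusion <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  confusion_counts(
    TP = sum(truth == "PD" & predicted == "PD"),
    TN = sum(truth == "ET" & predicted == "ET"),
    FP = sum(truth == "ET" & predicted == "PD"),
    FN = sum(truth == "PD" & predicted != "PD"))
}

#' Sensitivity, specificity and accuracy (percent)
#'
#' `sensitivity = 100 TP / (TP + FN)`, `specificity = 100 TN / (TN + FP)`,
#' `accuracy = 100 (TP + TN) / (TP + TN + FP + FN)`. A metric whose
#' denominator is zero is returned as `NA` (undefined), not an error.
#'
#' @param counts A [confusion_counts()].
#' @param variant `"standard"` (default) uses `(TP + TN)` in the accuracy
#'   numerator; `"printed"` reproduces a published variant with `TN` alone,
#'   retained for auditability only.
#' @return Named numeric vector `c(sensitivity, specificity, accuracy)` in
#'   percent.
#' @examples
#' confusion_metrics(confusion_counts(3, 2, 0, 0))  # 100 100 100
#' @export
confusion_metrics <- function(counts, variant = c("standard", "printed")) {
  stopifnot(inherits(counts, "confusion_counts"))
  variant <- match.arg(variant)
  with(counts, {
    total <- TP + TN + FP + FN
    acc_num <- if (variant == "standard") TP + TN else TN
    c(sensitivity = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
      specificity = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_,
      accuracy = if (total > 0) 100 * acc_num / total else NA_real_)
  })
}

#' Pooled-variance two-sample t-test p-value
#'
#' Two-sided Student t-test assuming equal variances (the Matlab `ttest2`
#' default used for the published group comparisons).
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values.
#' @return The two-sided p-value, or `NA` with a warning when the pooled
#'   variance is zero or a group is too small (test undefined).
#' @export
two_sample_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    warning("two_sample_t undefined: each group needs >= 2 values")
    return(NA_real_)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) return(1)
    warning("two_sample_t undefined: zero pooled variance with unequal means")
    return(NA_real_)
  }
  stats::t.test(group_a, group_b, var.equal = TRUE)$p.value
}

#' Separation distance between PD and ET fluctuation ratios
#'
#' `min(rf_pd) - max(rf_et)`: positive means the groups are separable by a
#' threshold between them, negative means they overlap.
#'
#' @param rf_pd,rf_et Nonempty numeric vectors of fluctuation ratios.
#' @return Numeric scalar.
#' @export
separation_distance <- function(rf_pd, rf_et) {
  if (!length(rf_pd) || !length(rf_et))
    stop("both groups must be nonempty")
  min(rf_pd) - max(rf_et)
}

#' Fluctuation ratios of a cohort
#'
#' @param cohort A cohort as produced by [generate_cohort()]: a list of
#'   subjects, each a list with `subject_id`, `label` (`"PD"`/`"ET"`), and
#'   `recordings` (named list of [tremor_recording()] per task).
#' @param axis,lags,spec,coverage,log_base Passed to [subject_features()].
#' @return Data frame with one row per subject: `subject_id`, `label`, `rf`,
#'   `predicted`. Subjects with undefined RF carry `NA`.
#' @export
cohort_rf <- function(cohort, axis = "x", lags = delay_pair(),
                      spec = filter_spec(), coverage = 0.95, log_base = 10) {
  rows <- lapply(cohort, function(subj) {
    sf <- subject_features(subj$recordings, axis = axis, lags = lags,
                           spec = spec, coverage = coverage,
                           log_base = log_base)
    data.frame(subject_id = subj$subject_id, label = subj$label,
               rf = sf$rf, predicted = sf$predicted_label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Delay-unit sweep over a cohort
#'
#' For every requested (d1, d2) pair and axis, computes per-group fluctuation
#' ratios, the pooled-variance t-test p-value between the PD and ET groups,
#' and the separation distance. Subjects with undefined RF are excluded from
#' the statistics; the exclusion count is reported per row and logged.
#'
#' @param cohort As in [cohort_rf()].
#' @param lag_grid List of [delay_pair()] objects (default
#'   [default_lag_grid()]).
#' @param axes Character vector of axes (default all three).
#' @param spec,coverage,log_base Passed through.
#' @return An object of class `cohort_sweep`: a data frame with columns `d1`,
#'   `d2`, `axis`, `p_value`, `separation_distance`, `n_pd`, `n_et`,
#'   `n_excluded`; the per-group RF lists are attached as the `"rf"`
#'   attribute (a list, one entry per row).
#' @export
delay_sweep <- function(cohort, lag_grid = default_lag_grid(),
                        axes = c("x", "y", "z"), spec = filter_spec(),
                        coverage = 0.95, log_base = 10) {
  stopifnot(all(axes %in% AXES))
  rows <- list(); rf_lists <- list(); i <- 0L
  for (lags in lag_grid) {
    for (axis in axes) {
      tab <- cohort_rf(cohort, axis = axis, lags = lags, spec = spec,
                       coverage = coverage, log_base = log_base)
      excluded <- sum(is.na(tab$rf))
      if (excluded > 0)
        message(excluded, " subject(s) with undefined RF excluded at d1=",
                lags$d1, " d2=", lags$d2, " axis=", axis)
      ok <- tab[!is.na(tab$rf), ]
      rf_pd <- ok$rf[ok$label == "PD"]
      rf_et <- ok$rf[ok$label == "ET"]
      i <- i + 1L
      rows[[i]] <- data.frame(
        d1 = lags$d1, d2 = lags$d2, axis = axis,
        p_value = if (length(rf_pd) >= 2 && length(rf_et) >= 2)
          two_sample_t(rf_pd, rf_et) else NA_real_,
        separation_distance = if (length(rf_pd) && length(rf_et))
          separation_distance(rf_pd, rf_et) else NA_real_,
        n_pd = length(rf_pd), n_et = length(rf_et), n_excluded = excluded,
        stringsAsFactors = FALSE)
      rf_lists[[i]] <- list(PD = rf_pd, ET = rf_et)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "rf") <- rf_lists
  class(out) <- c("cohort_sweep", class(out))
  out
}

#' End-to-end cohort classification performance
#'
#' Computes RF for every subject and evaluates the zero-threshold rule
#' against the cohort's true labels.
#'
#' @inheritParams cohort_rf
#' @param threshold RF decision threshold (default 0).
#' @param variant Accuracy variant, see [confusion_metrics()].
#' @return List with `table` (the [cohort_rf()] data frame), `counts`
#'   ([confusion_counts()]) and `metrics` (percent).
#' @export
evaluate_cohort <- function(cohort, axis = "x", lags = delay_pair(),
                            spec = filter_spec(), coverage = 0.95,
                            log_base = 10, threshold = 0,
                            variant = "standard") {
  tab <- cohort_rf(cohort, axis = axis, lags = lags, spec = spec,
                   coverage = coverage, log_base = log_base)
  predicted <- ifelse(is.na(tab$rf), "indeterminate",
                      vapply(tab$rf, classify_rf, character(1),
                             threshold = threshold))
  counts <- count_confusion(tab$label, predicted)
  list(table = transform(tab, predicted = predicted), counts = counts,
       metrics = confusion_metrics(counts, variant = variant))
}
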