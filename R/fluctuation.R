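#' Temporal fluctuation and fluctuation ratio
#'
#' The core statistic. A filtered angular-rate signal `s(n)` is mapped to the
#' two-dimensional delay-difference plane
#'
#'   f(n) = ( s(n + d1) - s(n),  s(n + d2) - s(n) ),   d1 < d2,
#'
#' and the "temporal fluctuation" TF is the area of the 95 % confidence
#' ellipse of the point cloud f(n), computed in closed form from the sample
#' covariance: `TF = pi * q * sqrt(det(Sigma))` with `q = qchisq(0.95, 2)`.
#' For a tremor band of 3-10 Hz the delay lags that maximise the differences
#' sit near the half-period range 0.05-0.17 s; the defaults d1 = 5, d2 = 20
#' samples (0.04 and 0.16 s at 125 samples/s) bracket it.
#'
#' The "fluctuation ratio" compares the resting and kinetic tasks of one
#' subject: `RF = log10(100 * TF_resting / TF_kinetic)`. Parkinsonian tremor
#' is rest-dominant (RF > 0), essential tremor action-dominant (RF < 0), so a
#' zero threshold classifies. RF is invariant to uniform rescaling of the
#' recordings (TF scales quadratically with amplitude in both numerator and
#' denominator) and the zero threshold is invariant to the logarithm base.
#'
#' @name fluctuation
NULL

#' Delay pair for the difference embedding
#'
#' @param d1,d2 Lags in samples, `0 < d1 < d2`; defaults 5 and 20 (0.04 and
#'   0.16 s at 125 samples/s).
#' @return An object of class `delay_pair`.
#' @export
delay_pair <- function(d1 = 5, d2 = 20) {
  if (d1 < 1 || d2 < 1 || d1 != round(d1) || d2 != round(d2))
    stop("lags must be positive integers")
  if (d1 >= d2) stop("need d1 < d2 (got d1 = ", d1, ", d2 = ", d2, ")")
  structure(list(d1 = as.integer(d1), d2 = as.integer(d2)),
            class = "delay_pair")
}

#' Two-delay difference embedding
#'
#' Point k (1-based) is `(s[k + d1] - s[k], s[k + d2] - s[k])` for
#' `k = 1 .. N - d2`.
#'
#' @param signal Numeric vector of length N > d2.
#' @param lags A [delay_pair()].
#' @return An object of class `embedded_cloud`: list with `points`
#'   ((N - d2) x 2 matrix) and `lags`.
#' @examples
#' delay_embed(c(0, 1, 2, 3, 4, 5), delay_pair(1, 2))$points  # all (1, 2)
#' @export
delay_embed <- function(signal, lags = delay_pair()) {
  stopifnot(inherits(lags, "delay_pair"))
  n <- length(signal)
  if (n <= lags$d2)
    stop("signal length (", n, ") must exceed d2 (", lags$d2, ")")
  idx <- seq_len(n - lags$d2)
  pts <- cbind(x = signal[idx + lags$d1] - signal[idx],
               y = signal[idx + lags$d2] - signal[idx])
  if (!all(is.finite(pts))) stop("non-finite values in embedding")
  structure(list(points = pts, lags = lags), class = "embedded_cloud")
}

#' Confidence ellipse of an embedded cloud
#'
#' The Gaussian confidence ellipse from the sample mean and covariance
#' (denominator n - 1): area `= pi * qchisq(coverage, 2) * sqrt(det(Sigma))`.
#' This closed form is deterministic; it is not a minimal-area empirical
#' coverage ellipse.
#'
#' @param cloud An [delay_embed()] result, or any n x 2 numeric matrix.
#' @param coverage Coverage probability (default 0.95).
#' @return An object of class `ellipse_summary`: list with `center` (length-2
#'   mean), `covariance` (2 x 2), `coverage`, `area` (the temporal
#'   fluctuation, in squared signal units) and `degenerate` (`TRUE` when the
#'   cloud has zero covariance determinant, in which case `area` is 0).
#' @export
ellipse_summary <- function(cloud, coverage = 0.95) {
  pts <- if (inherits(cloud, "embedded_cloud")) cloud$points else as.matrix(cloud)
  if (!is.numeric(pts) || ncol(pts) != 2)
    stop("cloud must be a two-column numeric point set")
  if (nrow(pts) < 3) stop("need at least 3 points for a covariance ellipse")
  if (!(coverage > 0 && coverage < 1)) stop("coverage must be in (0, 1)")
  ctr <- colMeans(pts)
  sigma <- stats::cov(pts)
  d <- det(sigma)
  degenerate <- !(d > 0)
  area <- if (degenerate) 0 else pi * stats::qchisq(coverage, df = 2) * sqrt(d)
  structure(list(center = ctr, covariance = sigma, coverage = coverage,
                 area = area, degenerate = degenerate),
            class = "ellipse_summary")
}

#' @export
print.ellipse_summary <- function(x, ...) {
  cat(sprintf("<ellipse_summary> %.0f%% coverage, area %.6g%s\n",
              100 * x$coverage, x$area,
              if (x$degenerate) " (degenerate cloud)" else ""))
  invisible(x)
}

#' Area of the confidence ellipse
#' @inheritParams ellipse_summary
#' @return The ellipse area (numeric scalar).
#' @export
ellipse_area <- function(cloud, coverage = 0.95)
  ellipse_summary(cloud, coverage)$area

#' Temporal fluctuation of a recording
#'
#' Composes band-pass filtering, axis selection, delay embedding and the
#' confidence-ellipse area.
#'
#' @param recording A [tremor_recording()].
#' @param axis Axis channel, default `"x"`.
#' @param lags A [delay_pair()].
#' @param spec A [filter_spec()].
#' @param coverage Ellipse coverage (default 0.95).
#' @return TF, a nonnegative scalar in squared signal units (0, with a
#'   `degenerate` attribute, when the filtered channel is constant over the
#'   embedding support).
#' @export
temporal_fluctuation <- function(recording, axis = c("x", "y", "z"),
                                 lags = delay_pair(), spec = filter_spec(),
                                 coverage = 0.95) {
  axis <- match.arg(axis)
  s <- bandpass(select_axis(recording, axis), recording$sampling_rate, spec)
  ell <- ellipse_summary(delay_embed(s, lags), coverage)
  structure(ell$area, degenerate = ell$degenerate)
}

#' Fluctuation ratio of resting to kinetic temporal fluctuation
#'
#' `RF = log10(100 * tf_resting / tf_kinetic)`. RF = 0 exactly when the
#' resting fluctuation is 1 % of the kinetic one; RF = 2 when they are equal.
#'
#' @param tf_resting,tf_kinetic Strictly positive temporal fluctuations.
#' @param log_base Logarithm base (default 10). The zero-threshold decision is
#'   base-invariant; the base only rescales RF.
#' @return RF, a finite scalar.
#' @export
fluctuation_ratio <- function(tf_resting, tf_kinetic, log_base = 10) {
  if (!is.finite(tf_resting) || !is.finite(tf_kinetic) ||
      tf_resting <= 0 || tf_kinetic <= 0)
    stop("fluctuation ratio requires strictly positive TF values")
  log(100 * tf_resting / tf_kinetic, base = log_base)
}

#' Classify a fluctuation ratio
#'
#' @param rf Finite fluctuation ratio.
#' @param threshold Decision threshold (default 0).
#' @return `"PD"` if `rf > threshold`, `"ET"` if below, `"indeterminate"` at
#'   equality.
#' @examples
#' classify_rf(0.7298)   # PD
#' classify_rf(-3.1430)  # ET
#' @export
classify_rf <- function(rf, threshold = 0) {
  if (!is.numeric(rf) || length(rf) != 1L || !is.finite(rf))
    stop("rf must be a single finite number")
  if (rf > threshold) "PD" else if (rf < threshold) "ET" else "indeterminate"
}

#' Per-subject features: TF per task, RF and predicted label
#'
#' @param recordings Named list of [tremor_recording()] objects, names from
#'   `{kinetic, postural, resting}` (postural optional).
#' @param axis,lags,spec,coverage,log_base Passed to
#'   [temporal_fluctuation()] / [fluctuation_ratio()].
#' @param threshold Classification threshold on RF (default 0).
#' @return An object of class `subject_features`: `subject_id`, `axis`,
#'   `tf_by_task` (named numeric), `rf` (`NA` when undefined: a required task
#'   missing or its TF not strictly positive) and `predicted_label`
#'   (`"indeterminate"` when `rf` is `NA` or equals the threshold).
#' @export
subject_features <- function(recordings, axis = "x", lags = delay_pair(),
                             spec = filter_spec(), coverage = 0.95,
                             log_base = 10, threshold = 0) {
  stopifnot(is.list(recordings), length(recordings) >= 1)
  bad <- setdiff(names(recordings), TASKS)
  if (length(bad)) stop("unknown task name(s): ", paste(bad, collapse = ", "))
  tf <- vapply(recordings, temporal_fluctuation, numeric(1),
               axis = axis, lags = lags, spec = spec, coverage = coverage)
  sid <- recordings[[1]]$subject_id
  rf <- NA_real_
  if (all(c("resting", "kinetic") %in% names(tf)) &&
      tf[["resting"]] > 0 && tf[["kinetic"]] > 0)
    rf <- fluctuation_ratio(tf[["resting"]], tf[["kinetic"]],
                            log_base = log_base)
  label <- if (is.na(rf)) "indeterminate" else classify_rf(rf, threshold)
  structure(list(subject_id = sid, axis = axis, tf_by_task = tf, rf = rf,
                 predicted_label = label),
            class = "subject_features")
}

#' @export
print.subject_features <- function(x, ...) {
  cat(sprintf("<subject_features> '%s' (axis %s): RF = %s -> %s\n",
              x$subject_id, x$axis,
              if (is.na(x$rf)) "undefined" else sprintf("%.4f", x$rf),
              x$predicted_label))
  invisible(x)
}
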