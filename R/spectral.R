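#' Autoregressive peak-frequency characterisation
#'
#' A 10-s filtered tremor signal is split into ten equal subsequences; each is
#' modelled as an AR(7) process fitted by the Yule-Walker method, the
#' parametric power spectrum is evaluated on a frequency grid, and the peak
#' frequency (spectrum argmax restricted to the 3-10 Hz tremor band) is
#' located per subsequence. The mean of the ten peaks summarises the
#' recording. In Parkinson's disease the resting-task peak frequency sits
#' below the kinetic-task one; in essential tremor it is stable across tasks.
#'
#' @name spectral_features
NULL

#' Partition a signal into equal-sized contiguous subsequences
#'
#' Subsequences are contiguous, non-overlapping and in order. When the length
#' is not divisible by `k`, the first `k - 1` subsequences get `floor(n / k)`
#' samples and the remainder is assigned to the final one.
#'
#' @param signal Numeric vector of length at least `k`.
#' @param k Number of subsequences (default 10).
#' @return List of `k` numeric vectors.
#' @examples
#' lengths(partition_equal(rnorm(1250)))  # ten of 125
#' partition_equal(1:10, k = 5)
#' @export
partition_equal <- function(signal, k = 10) {
  n <- length(signal)
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  if (n < k) stop("signal length (", n, ") shorter than k (", k, ")")
  size <- n %/% k
  starts <- (seq_len(k) - 1L) * size + 1L
  ends <- c(starts[-1L] - 1L, n)
  lapply(seq_len(k), function(i) signal[starts[i]:ends[i]])
}

# Yule-Walker AR fit on the biased autocovariance estimate. The biased
# estimator guarantees a positive-definite Toeplitz system; the subsequence
# mean is removed before fitting.
ar_yule_walker <- function(x, order) {
  n <- length(x)
  if (n <= order)
    stop("subsequence length (", n, ") must exceed the AR order (", order, ")")
  x <- x - mean(x)
  if (all(x == 0))
    stop("degenerate (constant) subsequence: AR model undefined")
  # biased autocovariance, lags 0..order
  r <- vapply(0:order, function(k)
    sum(x[seq_len(n - k)] * x[(k + 1):n]) / n, numeric(1))
  R <- stats::toeplitz(r[seq_len(order)])
  phi <- solve(R, r[2:(order + 1)])
  sigma2 <- r[1] - sum(phi * r[2:(order + 1)])
  list(coefficients = phi, noise_variance = max(sigma2, 0))
}

#' Parametric AR power spectral density of a subsequence
#'
#' Fits an AR model by Yule-Walker and evaluates
#' `sigma^2 / |1 - sum(phi_k exp(-i 2 pi f k / fs))|^2` on an equally spaced
#' frequency grid over `[0, fs/2]`.
#'
#' @param subseq Numeric vector, longer than `order` and not constant.
#' @param sampling_rate Samples per second.
#' @param order AR model order (default 7).
#' @param n_grid Number of grid points on `[0, Nyquist]` (default 512, i.e.
#'   ~0.12 Hz resolution at 125 samples/s).
#' @return List with `frequencies` (Hz) and `power` (nonnegative, arbitrary
#'   scale).
#' @export
ar_psd <- function(subseq, sampling_rate, order = 7, n_grid = 512) {
  if (order < 1 || order != round(order))
    stop("order must be a positive integer")
  fit <- ar_yule_walker(as.numeric(subseq), order)
  freq <- seq(0, sampling_rate / 2, length.out = n_grid)
  z <- exp(-2i * pi * outer(freq / sampling_rate, seq_len(order)))
  denom <- Mod(1 - as.vector(z %*% fit$coefficients))^2
  list(frequencies = freq, power = fit$noise_variance / denom)
}

#' Peak frequency of a power spectrum within a band
#'
#' @param frequencies,power Equal-length numeric vectors (a spectrum on a
#'   grid, e.g. from [ar_psd()]).
#' @param band Two-element numeric vector `(low, high)` in Hz; default the
#'   3-10 Hz tremor band. Restricting the search keeps spurious AR maxima at
#'   0 Hz or Nyquist from being reported.
#' @return Frequency (Hz) of the maximum power inside the band; ties break
#'   toward the lower frequency.
#' @export
peak_frequency <- function(frequencies, power, band = c(3, 10)) {
  stopifnot(length(frequencies) == length(power))
  in_band <- frequencies >= band[1] & frequencies <= band[2]
  if (!any(in_band))
    stop("frequency grid does not intersect the band [", band[1], ", ",
         band[2], "] Hz")
  f <- frequencies[in_band]
  p <- power[in_band]
  f[which.max(p)]  # which.max returns the first (lowest-frequency) maximum
}

#' Average peak frequency of a 10-s tremor signal
#'
#' Composes [partition_equal()], [ar_psd()] and [peak_frequency()] per
#' subsequence and averages the peaks. The signal is expected to be band-pass
#' filtered already.
#'
#' @param signal Numeric vector (one filtered axis channel).
#' @param sampling_rate Samples per second.
#' @param k Number of subsequences (default 10).
#' @param order AR order (default 7).
#' @param n_grid PSD grid size (default 512).
#' @param band Peak search band in Hz (default `c(3, 10)`).
#' @param axis,task Optional metadata carried into the result.
#' @return An object of class `peak_profile`: list with `subsequence_peaks`
#'   (length `k`, Hz), `average_peak` (Hz), `axis`, `task`.
#' @examples
#' fs <- 125; t <- (0:1249) / fs
#' s <- sin(2 * pi * 6 * t) + rnorm(1250, sd = 0.05)
#' average_peak_frequency(s, fs)$average_peak  # ~6 Hz
#' @export
average_peak_frequency <- function(signal, sampling_rate, k = 10, order = 7,
                                   n_grid = 512, band = c(3, 10),
                                   axis = "x", task = NA_character_) {
  peaks <- vapply(partition_equal(signal, k), function(sub) {
    spec <- ar_psd(sub, sampling_rate, order = order, n_grid = n_grid)
    peak_frequency(spec$frequencies, spec$power, band = band)
  }, numeric(1))
  structure(list(subsequence_peaks = peaks,
                 average_peak = mean(peaks),
                 axis = axis, task = task),
            class = "peak_profile")
}

#' @export
print.peak_profile <- function(x, ...) {
  cat(sprintf("<peak_profile> %d subsequence peaks, mean %.3f Hz (axis %s%s)\n",
              length(x$subsequence_peaks), x$average_peak, x$axis,
              if (is.na(x$task)) "" else paste0(", task ", x$task)))
  invisible(x)
}
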