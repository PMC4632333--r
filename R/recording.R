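#' Tremor recording data model and CSV input/output
#'
#' A `tremor_recording` holds one subject's one-task tri-axial angular-rate
#' time series from a finger-worn gyroscope, together with the sampling rate
#' and the task label under which it was recorded.
#'
#' @name recording
NULL

TASKS <- c("kinetic", "postural", "resting")
AXES <- c("x", "y", "z")

#' Construct a tremor recording
#'
#' @param x,y,z Numeric vectors of equal length: angular rate per axis
#'   (sensor units; the analysis is unit-agnostic).
#' @param task One of `"kinetic"`, `"postural"`, `"resting"`.
#' @param subject_id Character label for the subject.
#' @param sampling_rate Samples per second; default 125.
#'
#' @return An object of class `tremor_recording`: a list with elements
#'   `subject_id`, `task`, `sampling_rate`, `samples` (N x 3 matrix with
#'   columns x, y, z) and `duration_seconds`.
#' @examples
#' r <- tremor_recording(sin(1:100), cos(1:100), rep(0, 100), task = "resting")
#' r$duration_seconds
#' @export
tremor_recording <- function(x, y, z, task, subject_id = "anonymous",
                             sampling_rate = 125) {
  task <- match.arg(task, TASKS)
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(x)
  if (n < 1L) stop("recording must contain at least one sample")
  if (length(y) != n || length(z) != n)
    stop("all three channels must have identical length (x: ", n,
         ", y: ", length(y), ", z: ", length(z), ")")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  structure(
    list(subject_id = as.character(subject_id),
         task = task,
         sampling_rate = sampling_rate,
         samples = cbind(x = x, y = y, z = z),
         duration_seconds = n / sampling_rate),
    class = "tremor_recording")
}

#' @export
print.tremor_recording <- function(x, ...) {
  cat(sprintf("<tremor_recording> subject '%s', task '%s': %d samples @ %g Hz (%.3g s)\n",
              x$subject_id, x$task, nrow(x$samples), x$sampling_rate,
              x$duration_seconds))
  invisible(x)
}

#' Number of samples in a recording
#' @param recording A [tremor_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(recording) {
  stopifnot(inherits(recording, "tremor_recording"))
  nrow(recording$samples)
}

#' Extract one axis channel
#'
#' @param recording A [tremor_recording()].
#' @param axis One of `"x"`, `"y"`, `"z"`. The x axis is the package default
#'   throughout: rotation about it dominates during tremor with this sensor
#'   mount.
#' @return Numeric vector of length N.
#' @export
select_axis <- function(recording, axis = c("x", "y", "z")) {
  stopifnot(inherits(recording, "tremor_recording"))
  axis <- match.arg(axis)
  as.numeric(recording$samples[, axis])
}

#' Read a tremor recording from CSV
#'
#' The dialect is one header row `t,gx,gy,gz` (optionally followed by
#' `ax,ay,az` accelerometer columns, which are ignored), comma separated,
#' decimal point, one row per sample, `t` in seconds. Row order is preserved
#' exactly; no reordering, dropping or interpolation.
#'
#' @param path CSV file path.
#' @param subject_id,task Metadata attached to the recording.
#' @param sampling_rate Declared sampling rate (metadata; not inferred from
#'   the `t` column). If the declared rate disagrees with the median row
#'   spacing by more than 1 %, a warning is raised, not an error.
#' @return A [tremor_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, subject_id, task, sampling_rate = 125) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, colClasses = NA,
                    stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse CSV '", path, "': ",
                             conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty recording file: ", path)
  required <- c("t", "gx", "gy", "gz")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), c(required, "ax", "ay", "az"))
  if (length(extra))
    stop("unexpected column(s): ", paste(extra, collapse = ", "))
  for (col in required) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop("non-numeric value in column '", col, "' at row ",
           which(is.na(v))[1L])
    df[[col]] <- v
  }
  rec <- tremor_recording(df$gx, df$gy, df$gz, task = task,
                          subject_id = subject_id,
                          sampling_rate = sampling_rate)
  if (nrow(df) >= 2L) {
    dt <- stats::median(diff(df$t))
    if (is.finite(dt) && dt > 0 &&
        abs(1 / dt - sampling_rate) / sampling_rate > 0.01)
      warning(sprintf(
        "declared sampling rate %g Hz differs by > 1%% from the rate implied by the t column (%.4g Hz)",
        sampling_rate, 1 / dt))
  }
  rec
}

#' Write a tremor recording to CSV
#'
#' Inverse of [read_recording()]: emits the `t,gx,gy,gz` dialect with `t`
#' reconstructed from the sampling rate (starting at 0).
#'
#' @param recording A [tremor_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "tremor_recording"))
  n <- nrow(recording$samples)
  df <- data.frame(t = (seq_len(n) - 1L) / recording$sampling_rate,
                   gx = recording$samples[, "x"],
                   gy = recording$samples[, "y"],
                   gz = recording$samples[, "z"])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
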