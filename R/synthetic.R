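#' Synthetic tremor cohort generator
#'
#' Seeded generator of PD-like and ET-like multi-task gyroscope recordings
#' with the amplitude and frequency structure the discrimination method keys
#' on, so the full pipeline is testable without patient data. The class
#' profiles are synthetic configuration, clearly not estimates of any
#' clinical quantity.
#'
#' Tremor is modelled as an amplitude- and phase-modulated sinusoid (rather
#' than a draw from an AR process) so that the per-task centre frequency and
#' the rest/kinetic amplitude ratio — the two properties the classifier keys
#' on — are controlled directly, and the AR(7) spectral stage is exercised on
#' signals it did not assume. The kinetic task adds a sub-2-Hz high-amplitude
#' voluntary component that the 3 Hz high-pass edge must remove, making the
#' band-pass a load-bearing stage.
#'
#' @name synthetic_cohort
NULL

#' Synthetic tremor profile
#'
#' @param label `"PD"` or `"ET"`.
#' @param rest_amp,kinetic_amp,postural_amp Tremor amplitude per task (signal
#'   units, >= 0). PD default: rest-dominant (1.0 vs 0.1, ratio 10). ET
#'   default: action-dominant (0.05 vs 1.0, ratio 0.05).
#' @param rest_freq,kinetic_freq,postural_freq Centre frequency per task, Hz,
#'   inside (3, 10). PD default 4.5 / 6.5 / 5.5 (resting below kinetic); ET
#'   default 6 across tasks (stable).
#' @param frequency_jitter_sd Hz; slow wander of the instantaneous frequency.
#' @param amplitude_modulation_depth Fraction in \[0, 1); depth of the slow
#'   envelope modulation.
#' @param amplitude_modulation_rate Hz; rate of the envelope modulation.
#' @param broadband_noise_sd Signal units; white sensor noise.
#' @param voluntary_motion_amp,voluntary_motion_freq Amplitude and frequency
#'   (< 2 Hz) of the voluntary movement added in the kinetic task only.
#' @return An object of class `tremor_profile`.
#' @seealso [pd_profile()], [et_profile()] for the class defaults.
#' @export
tremor_profile <- function(label = c("PD", "ET"),
                           rest_amp, kinetic_amp, postural_amp,
                           rest_freq, kinetic_freq, postural_freq,
                           frequency_jitter_sd = 0.2,
                           amplitude_modulation_depth = 0.3,
                           amplitude_modulation_rate = 0.8,
                           broadband_noise_sd = 0.02,
                           voluntary_motion_amp = 5,
                           voluntary_motion_freq = 1) {
  label <- match.arg(label)
  amps <- c(rest_amp, kinetic_amp, postural_amp)
  freqs <- c(rest_freq, kinetic_freq, postural_freq)
  if (any(amps < 0)) stop("amplitudes must be nonnegative")
  if (any(freqs <= 3 | freqs >= 10))
    stop("centre frequencies must lie inside (3, 10) Hz")
  if (frequency_jitter_sd < 0 || broadband_noise_sd < 0)
    stop("noise scales must be nonnegative")
  if (amplitude_modulation_depth < 0 || amplitude_modulation_depth >= 1)
    stop("amplitude_modulation_depth must be in [0, 1)")
  if (voluntary_motion_freq >= 2)
    stop("voluntary_motion_freq must be below 2 Hz")
  structure(list(label = label,
                 rest_amp = rest_amp, kinetic_amp = kinetic_amp,
                 postural_amp = postural_amp,
                 rest_freq = rest_freq, kinetic_freq = kinetic_freq,
                 postural_freq = postural_freq,
                 frequency_jitter_sd = frequency_jitter_sd,
                 amplitude_modulation_depth = amplitude_modulation_depth,
                 amplitude_modulation_rate = amplitude_modulation_rate,
                 broadband_noise_sd = broadband_noise_sd,
                 voluntary_motion_amp = voluntary_motion_amp,
                 voluntary_motion_freq = voluntary_motion_freq),
            class = "tremor_profile")
}

#' PD-like class default profile
#'
#' Rest-dominant amplitude (rest/kinetic = 10) with a lower resting centre
#' frequency than kinetic — the rest-tremor phenotype the method assumes.
#' @return A [tremor_profile()].
#' @export
pd_profile <- function() {
  tremor_profile("PD",
                 rest_amp = 1.0, kinetic_amp = 0.1, postural_amp = 0.5,
                 rest_freq = 4.5, kinetic_freq = 6.5, postural_freq = 5.5)
}

#' ET-like class default profile
#'
#' Action-dominant amplitude (rest/kinetic = 0.05) with a stable ~6 Hz centre
#' frequency across tasks.
#' @return A [tremor_profile()].
#' @export
et_profile <- function() {
  tremor_profile("ET",
                 rest_amp = 0.05, kinetic_amp = 1.0, postural_amp = 0.8,
                 rest_freq = 6, kinetic_freq = 6, postural_freq = 6)
}

task_params <- function(profile, task) {
  switch(task,
         resting = c(amp = profile$rest_amp, freq = profile$rest_freq),
         kinetic = c(amp = profile$kinetic_amp, freq = profile$kinetic_freq),
         postural = c(amp = profile$postural_amp, freq = profile$postural_freq))
}

#' Generate one synthetic task recording
#'
#' The x channel is (kinetic task only) a low-frequency voluntary movement,
#' plus an amplitude-modulated sinusoid at the task's centre frequency with
#' slowly wandering instantaneous frequency, plus white noise. The y and z
#' channels are scaled-down copies (factors 0.4 and 0.25) with independent
#' noise, mimicking the dominance of rotation about the x axis.
#'
#' @param profile A [tremor_profile()].
#' @param task Task label.
#' @param seed Integer seed; the recording is a deterministic function of
#'   (profile, task, seed).
#' @param duration Seconds (default 10).
#' @param sampling_rate Samples per second (default 125).
#' @param subject_id Label for the recording.
#' @return A [tremor_recording()].
#' @export
generate_recording <- function(profile, task, seed, duration = 10,
                               sampling_rate = 125,
                               subject_id = profile$label) {
  stopifnot(inherits(profile, "tremor_profile"))
  task <- match.arg(task, TASKS)
  n <- round(duration * sampling_rate)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  tp <- task_params(profile, task)
  tt <- (seq_len(n) - 1) / sampling_rate
  # instantaneous frequency: centre + slow wander (25-sample moving average
  # of white noise, normalised to unit sd, scaled by the jitter sd)
  wander <- as.numeric(stats::filter(stats::rnorm(n), rep(0.2, 25),
                                     method = "convolution", sides = 1))
  wander[is.na(wander)] <- 0
  inst_freq <- tp[["freq"]] + profile$frequency_jitter_sd * wander
  phase <- 2 * pi * cumsum(inst_freq) / sampling_rate +
    stats::runif(1, 0, 2 * pi)
  envelope <- 1 + profile$amplitude_modulation_depth *
    sin(2 * pi * profile$amplitude_modulation_rate * tt + stats::runif(1, 0, 2 * pi))
  tremor <- tp[["amp"]] * envelope * sin(phase)
  voluntary <- if (task == "kinetic")
    profile$voluntary_motion_amp *
      sin(2 * pi * profile$voluntary_motion_freq * tt + stats::runif(1, 0, 2 * pi))
  else 0
  noise_sd <- profile$broadband_noise_sd
  x <- voluntary + tremor + stats::rnorm(n, sd = noise_sd)
  y <- 0.4 * (voluntary + tremor) + stats::rnorm(n, sd = noise_sd)
  z <- 0.25 * (voluntary + tremor) + stats::rnorm(n, sd = noise_sd)
  tremor_recording(x, y, z, task = task, subject_id = subject_id,
                   sampling_rate = sampling_rate)
}

#' Cohort specification
#'
#' @param n_pd,n_et Numbers of PD-like and ET-like subjects (defaults 32 and
#'   20, the size of a typical training cohort for this task).
#' @param seed Integer; fixes the entire cohort.
#' @param duration Seconds per recording (default 10).
#' @param sampling_rate Samples per second (default 125).
#' @param severity_sdlog Between-subject lognormal spread of overall tremor
#'   severity (one multiplier per subject scaling all three task amplitudes
#'   together; sd on the log scale, default 0.4).
#' @param task_amp_sdlog Lognormal spread of the per-task amplitude
#'   multipliers around the subject's severity (default 0.15). Severity is
#'   shared across tasks because tremor intensity scales a subject's tasks
#'   jointly; the rest/kinetic amplitude ratio is the class phenotype and so
#'   varies only by this smaller factor.
#' @param freq_sd Between-subject normal spread of the centre frequencies in
#'   Hz (default 0.4). For ET subjects one draw shifts all three tasks
#'   together, keeping the within-subject frequency stable across tasks; for
#'   PD subjects the per-task frequencies are drawn independently.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pd = 32, n_et = 20, seed = 1, duration = 10,
                        sampling_rate = 125, severity_sdlog = 0.4,
                        task_amp_sdlog = 0.15, freq_sd = 0.4) {
  if (n_pd < 0 || n_et < 0 || n_pd != round(n_pd) || n_et != round(n_et))
    stop("subject counts must be nonnegative integers")
  structure(list(n_pd = n_pd, n_et = n_et, seed = as.integer(seed),
                 duration = duration, sampling_rate = sampling_rate,
                 severity_sdlog = severity_sdlog,
                 task_amp_sdlog = task_amp_sdlog, freq_sd = freq_sd),
            class = "cohort_spec")
}

# deterministic per-subject/task sub-seed, kept below 2^31
subseed <- function(seed, i, j = 0L)
  (as.double(seed) * 48271 + i * 131 + j) %% 2147483647

clamp_freq <- function(f) pmin(9.5, pmax(3.2, f))

draw_profile <- function(base, spec, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  severity <- stats::rlnorm(1, sdlog = spec$severity_sdlog)
  amp_mult <- severity * stats::rlnorm(3, sdlog = spec$task_amp_sdlog)
  if (base$label == "ET") {
    shift <- stats::rnorm(1, sd = spec$freq_sd)
    freqs <- clamp_freq(c(base$rest_freq, base$kinetic_freq,
                          base$postural_freq) + shift)
  } else {
    freqs <- clamp_freq(c(base$rest_freq, base$kinetic_freq,
                          base$postural_freq) +
                          stats::rnorm(3, sd = spec$freq_sd))
  }
  tremor_profile(base$label,
                 rest_amp = base$rest_amp * amp_mult[1],
                 kinetic_amp = base$kinetic_amp * amp_mult[2],
                 postural_amp = base$postural_amp * amp_mult[3],
                 rest_freq = freqs[1], kinetic_freq = freqs[2],
                 postural_freq = freqs[3],
                 frequency_jitter_sd = base$frequency_jitter_sd,
                 amplitude_modulation_depth = base$amplitude_modulation_depth,
                 amplitude_modulation_rate = base$amplitude_modulation_rate,
                 broadband_noise_sd = base$broadband_noise_sd,
                 voluntary_motion_amp = base$voluntary_motion_amp,
                 voluntary_motion_freq = base$voluntary_motion_freq)
}

#' Generate a full synthetic cohort
#'
#' Each subject gets an individual profile drawn around the class defaults
#' ([pd_profile()], [et_profile()]) and all three task recordings. The whole
#' cohort is a deterministic function of the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param pd_base,et_base Class base profiles; override to stress-test (e.g.
#'   swapping the amplitude structure).
#' @return List of subjects; each subject is a list with `subject_id`,
#'   `label`, `profile` and `recordings` (named list kinetic/postural/resting
#'   of [tremor_recording()]).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_pd = 2, n_et = 1, seed = 7))
#' length(cohort)
#' names(cohort[[1]]$recordings)
#' @export
generate_cohort <- function(spec = cohort_spec(), pd_base = pd_profile(),
                            et_base = et_profile()) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- c(rep("PD", spec$n_pd), rep("ET", spec$n_et))
  lapply(seq_along(labels), function(i) {
    base <- if (labels[i] == "PD") pd_base else et_base
    prof <- draw_profile(base, spec, subseed(spec$seed, i))
    sid <- sprintf("%s%02d", labels[i],
                   if (labels[i] == "PD") i else i - spec$n_pd)
    recs <- lapply(seq_along(TASKS), function(j)
      generate_recording(prof, TASKS[j], seed = subseed(spec$seed, i, j),
                         duration = spec$duration,
                         sampling_rate = spec$sampling_rate,
                         subject_id = sid))
    names(recs) <- TASKS
    list(subject_id = sid, label = labels[i], profile = prof,
         recordings = recs)
  })
}
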