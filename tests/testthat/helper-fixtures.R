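# shared fixtures: all synthetic, built in code at test time

FS <- 125

sinusoid <- function(freq, duration = 10, fs = FS, amplitude = 1, phase = 0) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  amplitude * sin(2 * pi * freq * t + phase)
}

# magnitude response of the package's own band-pass design at given Hz
design_gain <- function(freq, spec = filter_spec(), fs = FS) {
  d <- butter_bandpass_sos(spec, fs)
  Mod(sos_response(d$sos, freq, fs))
}

# raw FFT periodogram argmax within a band: the independent spectral oracle
periodogram_peak <- function(x, fs = FS, band = c(3, 10)) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= band[1] & f <= band[2]
  f[keep][which.max(p[keep])]
}

# analytic AR(2) spectrum argmax on a fine grid (oracle for ar_psd)
ar2_true_peak <- function(phi, fs = FS, n_grid = 8192) {
  f <- seq(0, fs / 2, length.out = n_grid)
  z <- exp(-2i * pi * outer(f / fs, 1:2))
  p <- 1 / Mod(1 - as.vector(z %*% phi))^2
  f[which.max(p)]
}

# AR(2) with conjugate poles at radius r, frequency f0: realization + coefs
ar2_process <- function(f0, r = 0.95, n = 4096, fs = FS) {
  theta <- 2 * pi * f0 / fs
  phi <- c(2 * r * cos(theta), -r^2)
  x <- as.numeric(stats::filter(stats::rnorm(n + 200), phi,
                                method = "recursive"))[-(1:200)]
  list(x = x, phi = phi)
}

tiny_cohort <- function(n_pd = 2, n_et = 2, seed = 5)
  generate_cohort(cohort_spec(n_pd = n_pd, n_et = n_et, seed = seed))

# class base profiles with the amplitude structure exchanged (labels kept)
swapped_bases <- function() {
  pd <- pd_profile(); et <- et_profile()
  list(
    pd = tremor_profile("PD", rest_amp = et$rest_amp,
                        kinetic_amp = et$kinetic_amp,
                        postural_amp = et$postural_amp,
                        rest_freq = pd$rest_freq,
                        kinetic_freq = pd$kinetic_freq,
                        postural_freq = pd$postural_freq),
    et = tremor_profile("ET", rest_amp = pd$rest_amp,
                        kinetic_amp = pd$kinetic_amp,
                        postural_amp = pd$postural_amp,
                        rest_freq = et$rest_freq,
                        kinetic_freq = et$kinetic_freq,
                        postural_freq = et$postural_freq))
}
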