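---
title: "Temporal-fluctuation analysis of tremor recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-fluctuation analysis of tremor recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorfluct)
```

## The problem and the statistic

Parkinsonian (PD) and essential tremor (ET) overlap in frequency (both fall
inside roughly 4–8 Hz) but differ in *task dependence*: PD tremor is
rest-dominant and its resting frequency sits below its kinetic frequency,
whereas ET tremor is action-dominant with a task-stable frequency. A
frequency feature alone therefore separates the tasks within PD but not PD
from ET; a usable discriminator must couple amplitude and time structure.

`tremorfluct` quantifies the *temporal fluctuation* (TF) of a band-pass
filtered angular-rate signal $s(n)$ through the two-delay difference map

$$ f(n) = \big(s(n+d_1) - s(n),\; s(n+d_2) - s(n)\big), \qquad d_1 < d_2, $$

summarised by the area of the 95 % confidence ellipse of the point cloud
$f(n)$. For a signal confined to 3–10 Hz the differences are largest when the
lag is near a half period, i.e. lags between $1/(2\cdot 10) = 0.05$ s and
$1/(2\cdot 3) \approx 0.17$ s; the defaults $d_1 = 5$ and $d_2 = 20$ samples
(0.04 s and 0.16 s at 125 samples/s) bracket that range. The per-subject
classifier is the *fluctuation ratio*

$$ RF = \log_{10}\!\frac{100\, TF_{\text{resting}}}{TF_{\text{kinetic}}}, $$

with RF > 0 classified PD, RF < 0 classified ET, RF = 0 (resting fluctuation
exactly 1 % of kinetic) indeterminate. Two invariances make RF robust to
calibration: TF scales quadratically with signal amplitude, so any common
gain or unit change cancels in the ratio, and the zero threshold is invariant
to the logarithm base.

### Assumptions

* The tremor of interest lies in 3–10 Hz and the chosen axis channel carries
  it (x by default — rotation about that axis dominates with a finger-mounted
  sensor).
* Both tasks of a subject are recorded with the same device and gain
  (otherwise the rescaling invariance of RF does not apply).
* The embedded cloud is summarised by its second moments; the Gaussian
  confidence ellipse is a covariance summary, not a density estimate.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `low_cutoff`, `high_cutoff` | 3, 10 | Hz | tremor band; the 3 Hz edge removes the high-amplitude voluntary component of the kinetic task |
| `design_order` | 10 | – | order handed to the band-pass designer (2×10 poles realized) |
| `zero_phase` | `TRUE` | – | forward–backward application; TF is a shape statistic, phase distortion is nuisance |
| `d1`, `d2` | 5, 20 | samples | near-half-period lags for a 3–10 Hz band at 125 samples/s |
| `coverage` | 0.95 | – | ellipse coverage probability; area = $\pi\,\chi^2_{0.95}(2)\sqrt{\det\Sigma}$ |
| `log_base` | 10 | – | RF scale; threshold at 0 is base-invariant |
| AR `order` | 7 | – | parametric spectral model per subsequence |
| `k` | 10 | – | equal subsequences per 10-s signal |
| `n_grid` | 512 | – | PSD grid on [0, Nyquist]; ~0.12 Hz resolution, far below the inter-task frequency differences of interest |

## Numerical choices

**Filter realization.** No DSP package is assumed: the designer builds the
analog Butterworth prototype, applies the lowpass→bandpass transform and the
bilinear transform (with frequency pre-warping), and *always* realizes the
filter as cascaded biquads — a 20-pole band-pass in direct form is
numerically unstable at this band/rate ratio. The design was cross-checked
against an independent reference implementation; frozen magnitude-response
values at nine frequencies live in the test suite. "10th order" is
interpreted as the order parameter of the band-pass designer (2×10 realized
poles), the common usage in Matlab-style workflows; both the order and a
single-pass causal mode are configurable because the original processing
choice is not recoverable. Zero-phase filtering mirrors the signal at both
ends (odd reflection) so start-up transients decay in the padding.

**Yule–Walker AR fit.** The autocovariance uses the biased ($1/n$) estimator,
which guarantees a positive-definite Toeplitz system; the subsequence mean is
removed before fitting. The spectrum is $\sigma^2 / |A(e^{-i\omega})|^2$ on
512 grid points; only relative power matters for the peak, so no density
normalisation is applied. The peak search is restricted to 3–10 Hz because
AR spectra can place spurious maxima at 0 Hz or Nyquist; ties break toward
the lower frequency (deterministic). Constant subsequences are an error (the
model is undefined), not a silent zero.

**Ellipse definition.** TF is the *Gaussian* 95 % confidence ellipse area
from the sample covariance (denominator $n-1$), in closed form. An empirical
minimal-area ellipse covering 95 % of the points is a different estimator
that cannot be distinguished from the covariance form without the original
recordings; the covariance form is deterministic, standard, and matches the
"confidence ellipse" terminology, so it is the implemented definition. A
cloud with zero covariance determinant yields area 0 with a degeneracy flag
rather than an error; fewer than 3 points is an error.

**Undefined RF.** If either task's TF is not strictly positive (or a task is
missing), RF is undefined and the subject is marked indeterminate and
excluded from cohort statistics with a logged count. No epsilon flooring is
applied: flooring would silently manufacture classifications for flat
signals.

**Accuracy formula.** The standard accuracy $(TP+TN)/(TP+TN+FP+FN)$ is the
default. A published variant with $TN$ alone in the numerator is
internally inconsistent with a perfect 3 PD + 2 ET validation being reported
as 100 % accurate, and is retained only behind
`confusion_metrics(variant = "printed")` for auditability.

**Group t-tests.** Pooled-variance (equal-variance) two-sided t-tests, the
Matlab `ttest2` default that produced the published comparisons. When TF
itself (rather than RF) is compared between groups, work on `log10(TF)`: TF
is right-skewed by its quadratic amplitude dependence.

## The synthetic cohort: what it emulates and what it does not

No patient recordings are distributable, so the package ships a seeded
generator whose defaults *are* the stated world of the method:

* tremor = amplitude-modulated sinusoid (modulation depth 0.3 at 0.8 Hz)
  with slowly wandering instantaneous frequency (sd 0.2 Hz), plus white
  sensor noise (sd 0.02 signal units);
* PD class: rest/kinetic amplitude ratio 10 (1.0 vs 0.1), resting centre
  frequency 4.5 Hz below the kinetic 6.5 Hz;
* ET class: rest/kinetic ratio 0.05 (0.05 vs 1.0), centre frequency 6 Hz in
  every task;
* kinetic task adds a 1 Hz voluntary component of amplitude 5 — five times
  the tremor — which the 3 Hz filter edge must remove, making the band-pass a
  load-bearing, testable stage;
* y and z channels are scaled copies (0.4, 0.25) of x with independent noise.

Between-subject variability is structured, and that structure matters: one
lognormal *severity* multiplier (sdlog 0.4) scales all three task amplitudes
of a subject jointly, and small per-task multipliers (sdlog 0.15) perturb the
ratio. Tremor severity plausibly scales a subject's tasks together, while the
rest/kinetic ratio is the class phenotype; drawing task amplitudes
independently would let the phenotype itself wander across the decision
boundary and would test the generator's noise, not the method. Centre
frequencies get a per-task normal jitter (sd 0.4 Hz) for PD but a single
shared shift for ET, reproducing the qualitative significance pattern
(kinetic-vs-resting frequency differs in PD, not in ET). Tremor is modelled
as a modulated sinusoid rather than an AR-process draw deliberately, so the
AR(7) spectral stage runs on data it did not assume.

What the generator does *not* emulate: harmonics and waveform asymmetry,
re-emergent rest tremor latency, amplitude nonstationarity beyond one
modulation tone, sensor drift or clipping, or any clinical covariate (age,
TRS, medication state). A green end-to-end test therefore establishes that
the pipeline recovers the class structure it defines — amplitude-ratio
dominance in the stated band — not clinical validity on real patients.

## Degenerate inputs and edge behaviour

* All-zero (or constant) recordings: TF = 0 with a degeneracy flag; RF
  undefined; subject indeterminate.
* Signals shorter than d₂ + 1 samples cannot be embedded; shorter than ~3×
  the filter order cannot be filtered — both are errors, not warnings.
* Sampling-rate metadata disagreeing with the CSV time column by more than
  1 % warns but proceeds (the declared rate wins; the rate is metadata, never
  inferred).
* Equal-sized partition with a non-divisible length assigns the remainder to
  the final subsequence.

## Known limitations

* The confidence-ellipse variant (covariance-based vs empirical coverage)
  and the realized pole count of the original filter are unrecoverable
  design ambiguities; both are surfaced as options with documented defaults.
* RF needs both resting and kinetic tasks; no single-task fallback is
  offered (the resting TF alone separates groups only weakly).
* The classifier is a fixed zero-threshold rule; no calibration on training
  data is performed or supported.
* Cohort-level conclusions from the synthetic generator are qualitative:
  effect sizes are set by its configuration, not estimated from patients.
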