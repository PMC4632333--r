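# tremorfluct

Discrimination of Parkinsonian (PD) from essential tremor (ET) using short
gyroscope recordings from a finger-worn inertial sensor.

PD and ET are the two most common tremor disorders and are frequently
confused clinically, yet their treatments differ. Their kinematic signatures
differ in a usable way: Parkinsonian tremor is **rest-dominant** (large at
rest, suppressed during voluntary movement, with a lower resting tremor
frequency), while essential tremor is **action-dominant** with a stable
frequency across tasks. `tremorfluct` implements a time-domain statistic that
turns this asymmetry into a single-number classifier, for researchers working
with wearable-sensor movement-disorder data.

## The method

Each subject performs three 10-s tasks (kinetic: repeated nose-target
movement; postural: arms outstretched; resting: arms relaxed) while a 6-axis
IMU on the index finger records tri-axial angular rate at 125 samples/s. For
one axis channel *s(n)* (default: x, the axis with the largest tremor
rotation):

1. **Band-pass filter** to 3–10 Hz (10th-order Butterworth, cascaded
   second-order sections, zero-phase by default). This isolates the tremor
   band and removes the large sub-2-Hz voluntary component of the kinetic
   task.
2. **Delay-difference embedding** with lags d₁ < d₂ (defaults 5 and 20
   samples):

       f(n) = ( s(n + d₁) − s(n),  s(n + d₂) − s(n) )

3. **Temporal fluctuation (TF)**: the area of the 95 % confidence ellipse of
   the point cloud f(n), computed in closed form from the sample covariance
   Σ as TF = π · χ²₀.₉₅(2) · √det Σ.
4. **Fluctuation ratio (RF)** between the resting and kinetic tasks:

       RF = log₁₀( 100 · TF_resting / TF_kinetic )

   RF > 0 → PD, RF < 0 → ET (RF = 0 means the resting fluctuation is exactly
   1 % of the kinetic one; the threshold is invariant to the log base and to
   uniform rescaling of the signals).

Supporting machinery: AR(7) Yule–Walker peak-frequency profiles over ten
signal subsequences (the task-dependent frequency shift seen in PD),
pooled-variance two-sample t-tests, delay-unit sweeps with separation
distances, confusion-matrix metrics (PD positive), a seeded synthetic cohort
generator, and a CLI.

## Worked example

```r
library(tremorfluct)

cohort <- generate_cohort(cohort_spec(n_pd = 3, n_et = 2, seed = 42))
subj <- cohort[[1]]                       # a PD-like subject
sf <- subject_features(subj$recordings, axis = "x")
sf$tf_by_task
#>     kinetic    postural     resting
#>  0.02546582  1.16099505 10.03422626
sf
#> <subject_features> 'PD01' (axis x): RF = 4.5955 -> PD

res <- evaluate_cohort(cohort)
res$table
#>   subject_id label         rf predicted
#> 1       PD01    PD  4.5955263        PD
#> 2       PD02    PD  4.6654095        PD
#> 3       PD03    PD  4.1922120        PD
#> 4       ET01    ET -0.5492129        ET
#> 5       ET02    ET -0.8160934        ET
res$metrics
#> sensitivity specificity    accuracy
#>         100         100         100
```

The PD-like subject's resting ellipse area (10.03 squared signal units) is
~400× the kinetic one (0.025), giving RF ≈ +4.6: strongly rest-dominant,
classified PD. The ET-like subjects' resting fluctuation is a fraction of
their kinetic one, RF < 0, classified ET.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "tremorfluct", package = "tremorfluct"))')
Rscript $CLI simulate --n-pd 32 --n-et 20 --seed 1 --out cohort/
Rscript $CLI rf       --manifest cohort/manifest.csv --out rf.csv
Rscript $CLI sweep    --manifest cohort/manifest.csv --out sweep.csv
Rscript $CLI evaluate --manifest cohort/manifest.csv
```

Recordings are CSV (`t,gx,gy,gz`, one row per sample); all tabular output is
headered CSV; every run logs the filter spec, delay pair and coverage used to
standard error.

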