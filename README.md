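# plumekin

Analysis pipeline for head-mounted sensor recordings from mice performing
odor-guided search in a turbulent plume. In turbulence, odor arrives as
discrete filaments; each contact with the animal's gas sensor is a "plume
encounter", and the scientific question is how encounters modulate active
sensing: head-pitch oscillation amplitude and frequency, head height, body
orientation toward the source, and lateral head scanning (yaw).

The pipeline has four analytic stages plus a synthetic-data generator with
exact ground truth:

1. **Plume-event detection** — the metal-oxide sensor voltage is zero-phase
   low-pass filtered (5 Hz) and deconvolved with a unit-area
   difference-of-exponentials kernel
   `k(t) = (exp(-t/τ_decay) - exp(-t/τ_rise)) / (τ_decay - τ_rise)`
   (τ_rise = 0.02 s, τ_decay = 10 s; Tikhonov-regularized frequency-domain
   inverse). Onsets are threshold crossings of the ratio of forward to
   reverse least-squares slopes of the cumulative sum, computed over 1-s
   segments on each side of every sample; the threshold can be calibrated
   on blank sessions to a target false-positive rate. Group-data filters
   drop onsets within 5 s of the previous kept onset, onsets with the
   animal within 15 px of the source, and onsets whose ±5 s window leaves
   the arena interval.
2. **Head motion** — accelerometer voltages are calibrated to g, low-pass
   filtered (20 Hz) and differentiated to jerk; an analytic Morlet
   continuous wavelet transform yields band power and per-sample dominant
   frequency in the 5–14 Hz active-search band. Head raised/lowered states
   come from the 1-s moving-median Z−X signal, thresholded at μ₃ − σ₃ of
   the largest-mean component of a three-Gaussian mixture (BIC-checked).
3. **Kinematics** — pose-estimator keypoints (nose, neck, body; likelihoods
   below 0.9 masked) give the signed body angle with respect to the port
   (0° = aimed at the port; clockwise-on-screen positive), the egocentric
   head-yaw angle (left positive), speed, and yaw zero-crossing times.
4. **Peri-event statistics** — every scalar or angular series is aligned to
   the retained onsets (±5 s windows) and to an equal number of surrogate
   windows drawn uniformly from in-arena times excluding ±1 s around real
   onsets. Per-trajectory 1-s-bin means are compared real-vs-random with
   two-sample Kolmogorov–Smirnov tests (one p per bin, uncorrected);
   angles are summarized by circular means and resultant-vector strengths
   R, with paired Wilcoxon signed-rank tests on before/after R; yaw zero
   crossings become per-trajectory z-scored rolling rates.

## Worked example

Generate a synthetic cohort with the default injected modulations (pitch
amplitude ×1.5 for 1 s before each encounter, ×0.6 for 1 s after, +3 Hz
pitch frequency and a 0.2 g head drop for 3 s after, heading-noise SD ×0.3
for 3 s after) and run the full analysis:

```r
library(plumekin)
cfg    <- analysis_config()
truth  <- ground_truth()                      # default effect condition
cohort <- gen_cohort(cfg, truth, n_trials = 12, seed = 42)
res    <- analyze_cohort(cohort, cfg, seed = 43)
res
#> <cohort_analysis> 12 trials, 67 pooled events
#>   body-angle paired R: real p = 1.15e-12, random p = 0.0111
#>   band_power     significant bins (p < 0.05): 4 / 10
#>   dominant_freq  significant bins (p < 0.05): 8 / 10
#>   head_d         significant bins (p < 0.05): 6 / 10
#>   crossing_rate  significant bins (p < 0.05): 1 / 10
```

The per-bin band-power table shows the injected structure exactly where it
was placed — real power far above random in the second before the
encounter (the amplitude boost) and below it in the second after (the
drop):

```r
tab <- res$bins$band_power
data.frame(bin = tab$bin, p = signif(tab$p_value, 3),
           real = signif(tab$real_mean, 3), random = signif(tab$random_mean, 3))
#>       bin        p real random
#>  -5 to -4 1.35e-03 19.8   23.5
#>  ...
#>   -1 to 0 4.87e-25 38.2   21.5
#>    0 to 1 9.74e-10 16.6   20.6
#>  ...
```

The body-angle paired test (`res$body_R$real`) is strongly significant with
a positive median R difference: heading variability collapses after the
encounter. The dominant-frequency and head-height tables are significant in
the 0–3 s bins, where the frequency shift and head drop were injected.
(Surrogate-window statistics can retain mild encounter-locked structure in
this synthetic regime — encounters and their 3-s effect windows occupy a
sizable fraction of each trial, so random windows overlap them more often
than in sparse real recordings.)

Detected onsets track ground truth to well under a quarter second:

```r
as.data.frame(res$processed[[1]]$events)[1:3, 1:2]
#>   onset_s ratio
#> 1    5.98 1.751
#> 2   16.30 1.755
#> 3   44.41 1.752
cohort[[1]]$truth$true_onsets[1:3]
#> [1]  6.17 16.49 44.60
```

A file-based version of the same pipeline (CSV in, CSV out, with a JSON
run manifest) is available through `run_all()` / `stage_generate()` /
`stage_detect()` / `stage_headmotion()` / `stage_kinematics()` /
`stage_analyze()`, or from a shell via the thin wrapper
`inst/cli/plumekin.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","plumekin.R",package="plumekin"))')" \
  run --out out/ --trials 12 --seed 42
```

See the vignette (`vignettes/plume-encounter-analysis.Rmd`) for the model,
the numerical choices, and what the synthetic validation does and does not
establish about real data.

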