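# chronodelay

Analysis toolkit for mouse studies of **dim light in the evening (DLE)** —
a 20-lux, 4-hour extension of the light phase (ZT 12–16) appended to a
standard 200-lux 12:12 light/dark cycle. Exposure of this kind phase-delays
circadian behaviour and physiology, realigns sleep, shifts peripheral
molecular clocks, and reorganizes sleep-dependent memory performance.
chronodelay is written for chronobiologists and sleep researchers who want
the full analysis chain of such an experiment as tested, reusable R code:

1. **Locomotor phase markers** from passive-infrared (PIR) counts at 10-s
   resolution: daily activity *onset* and *offset* as crossings of a short
   (3-h) and long (24-h) moving average of the 1-h-smoothed series
   (upward crossing where `Δ[i-1] Δ[i] < 0` with `Δ[i-1] < 0`), and the
   *midpoint* as the time where activity in the preceding 8 h equals that
   in the subsequent 8 h. Phase delays (treatment minus baseline day sets)
   and the free-running period τ (24 h + onset drift slope under constant
   darkness) follow.
2. **Immobility-defined sleep**: a 10-s bin is asleep iff it lies in a run
   of ≥ 4 zero-count bins (≥ 40 s immobility); sleep proportion, bout
   durations in 4-h bins, and sleep history preceding arbitrary events.
3. **In vivo bioluminescence rhythms** from shutter-gated photon counts
   (1 closed minute per 15): background correction, circadian-band (16–32 h)
   wavelet detrending, per-cycle acrophase φ, period, and signal-to-noise
   ratio; Morlet wavelet power spectra of activity for circadian (~24 h)
   and ultradian (~8 h) components.
4. **qPCR expression rhythms**: 2^−ΔCt against the geometric mean of two
   housekeeping genes, per-condition peak normalization to 2^−ΔΔCt, cosinor
   acrophase with center-of-gravity cross-check, phase shifts
   Δφ = φ_DLE − φ_LD wrapped to (−12, 12], and pooled one-sample t tests.
5. **Sleep history and recognition memory**: the sliding-window scan of
   R²(t) between prior-sleep proportion (widths 10–180 min) and recognition
   ratio across the 8 trial-type cell means, plus the mixed model
   `ratio ~ sleep2h + (1 | mouse)` with a likelihood-ratio χ² test and a
   parametric-bootstrap confidence interval for the sleep effect.

A **synthetic-data generator** (two-state Poisson activity with first-order
re-entrainment dynamics and per-marker delay targets, shutter-gated
luciferase traces, cosine Ct tables, sleep-coupled recognition trials)
emulates every input modality with known ground truth, so the whole chain
is testable by parameter recovery — no data download is required anywhere.

## Worked example

Simulate the wild-type DLE cohort (12 mice, 7 d LD baseline + 13 d DLE),
extract phase markers, and estimate the delays:

```r
library(chronodelay)

wt   <- simulate_cohort("wt_dle", 12, seed = 1)
tabs <- lapply(wt, phase_markers)
phase_delay(tabs, baseline_days = 2:7, treatment_days = 16:20, "onset_zt")
#> Phase delay (onset): 3.48 +/- 0.01 h (n = 12)
phase_delay(tabs, 2:7, 16:20, "midpoint_zt")
#> Phase delay (midpoint): 2.51 +/- 0.01 h (n = 12)
phase_delay(tabs, 2:7, 16:20, "offset_zt")
#> Phase delay (offset): 2.44 +/- 0.01 h (n = 12)
```

The recovered group delays sit within sampling error of the programmed
steady-state targets (3.59, 2.57 and 2.52 h; the ~0.1-h shortfall is the
re-entrainment dynamics still converging over the last 5 DLE days).
Sleep scoring and a bioluminescence trace:

```r
s <- score_sleep(wt[[1]])
head(binned_sleep_summary(s), 3)
#>   bin_start_h proportion bout_count mean_bout_s
#> 1           0  0.7958333        105   110.19048
#> 2           4  0.7555556         99   109.09091
#> 3           8  0.7986111        120    95.58333

tr <- generate_bioluminescence(phi_true = 10, tau_true = 23.7, days = 5, seed = 1)
acrophase(dwt_detrend(background_correct(tr)))
#> Rhythm acrophase: 9.34 h (circular mean of 4 cycle peaks)
```

(The acrophase is read in external clock time while the 23.7-h rhythm
free-runs, so per-cycle peaks drift 0.3 h earlier per day; 9.34 h is the
circular mean over the four interior cycles.) The sleep–memory analysis:

```r
rec <- generate_recognition(seed = 1)   # 11 mice x 8 trials, calibrated reference preset
window_scan(rec)
#> Sleep-history window scan: 18 widths
#> R2 at 120 min: 0.946; 95% plateau reached at 100 min
lmm_sleep_effect(rec, n_boot = 1000, seed = 1)
#> Mixed model ratio ~ sleep + (1 | mouse): slope = 0.395, LR chi2(1) = 90.45, p = 1.897e-21
#> Parametric-bootstrap 95% CI (1000 iterations): [0.340, 0.455]
```

R² between prior sleep and performance rises with window width and
plateaus near 0.9 by ~2 h, and the mixed model confirms the sleep effect
with a bootstrap interval excluding zero. `run_experiment(run_config())`
chains all five stages from one master seed and writes a summary JSON of
every recovered quantity next to its programmed truth.

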