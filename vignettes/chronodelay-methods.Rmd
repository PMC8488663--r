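---
title: "Models and methods behind chronodelay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chronodelay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronodelay)
```

chronodelay implements the complete analysis chain of a mouse
dim-light-in-the-evening (DLE) experiment — locomotor phase markers,
immobility-defined sleep, molecular-rhythm acrophases, in vivo
bioluminescence rhythms, and the sleep-history/memory window scan — together
with a synthetic-data generator whose ground truth makes every stage
testable by parameter recovery. This vignette explains each model, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic data do and do not emulate.

## The lighting protocols

Four protocols are supported (`make_schedule()`): standard 12:12 LD (200 lx
light phase), DLE (200 lx for ZT 0–12, 20 lx for ZT 12–16, darkness for
ZT 16–24), a 16:8 long day (200 lx for ZT 0–16), and constant darkness
(DD). Schedules concatenate day-wise, so a 7-day LD baseline followed by a
13-day DLE block is a single recording.

## The activity generator

Passive-infrared (PIR) counts in 10-s bins are drawn from a two-state
Poisson model: a nightly *active window* with mean rate `lambda_active`
(default 2 counts/bin) and a rest state with `lambda_rest` (default 0.15).
The rest rate was fixed analytically: with the four-bin immobility rule
below, the probability that a rest bin is scored asleep is
`p (1 - q^2 (1 + 2p + 3p^2))` with `p = exp(-lambda_rest)` and `q = 1 - p`;
`lambda_rest = 0.15` puts the light-phase sleep proportion near 0.78, inside
the 0.6–0.8 range reported for PIR-defined sleep in mice, whereas very small
rates (≤ 0.05) would push it above 0.9.

Phase delays are imposed on the window edges. Each marker (onset, midpoint,
offset) has its own steady-state delay target, because the experimental
arms being emulated delay onsets more than offsets (wild type under DLE:
3.59 / 2.57 / 2.52 h; melanopsin-knockout: 2.74 / 2.32 / 1.61 h; 16:8 long
day: an additional 2.21 / 0.99 / 0.64 h). After a protocol switch the delay
approaches its target by the first-order recursion
`psi[d+1] = psi[d] + k (psi_target - psi[d])` with `k = 0.3`/day — actogram
transitions take about a week, but no rate is reported, so `k` is a free
default. Under DD the window drifts by `tau_h - 24` h/day (default
`tau_h = 23.7`). The midpoint target is realized by a two-segment rate
profile that places the *median* of the nightly activity at the programmed
time; the 8-h balance rule used by the analysis finds exactly that median
whenever the whole active window fits inside ±8 h.

Two further features matter:

* **Window-edge calibration.** The moving-average crossing rules detect an
  onset where the short average crosses the daily mean level, which sits at
  a duty-cycle–dependent offset from the raw rate step (about 0.2 h for a
  10.9-h window, 0.4 h for a 9.4-h window). The generator therefore
  calibrates each day's window edges, by running the detection rules on the
  noiseless rate, so that the *detectable* markers — the stored ground
  truth — land exactly on the programmed times. Without this, "programmed
  delay" would silently mean different things for different window
  durations.
* **Day-to-day phase jitter** (`phase_jitter_sd_h`, default 0). A rigid
  normal jitter of all three markers emulates the day-to-day onset scatter
  visible in single-animal actograms. The cohort presets leave it at 0 (the
  published group delays are means over days, and the arms are defined by
  their steady-state targets); the recognition-memory preset sets it to 1 h
  so that sleep history genuinely varies between trials of the same type —
  without it, the 2-h sleep proportion before a trial is almost
  deterministic and the window scan saturates at the shortest width.

Dim light (0 < lux < 200) multiplies the concurrent rate by `masking`
(default 0.8), emulating negative masking by the 20-lx evening light.
An optional ultradian modulation (`ultradian_depth`, default 0; period 8 h,
anchored at the nightly onset) produces the multi-modal night activity used
for wavelet power comparisons.

## Phase markers

Raw counts are smoothed with a centered 1-h moving average; onsets/offsets
are crossings of a 3-h and a 24-h moving average of the smoothed series
(first upward and last downward crossing after the onset within each day
window), and midpoints are the sign change of the preceding-8-h minus
subsequent-8-h activity balance. Choices the method description leaves
open:

* Moving averages are *centered* (trailing averages would bias every marker
  late by half a window; delays, being differences, are invariant either
  way). Even windows are widened by one bin.
* Day windows span ZT 6–30, matching the double-plotted actogram axis, so
  the nocturnal bout is never split at midnight.
* Runs of exact zeros in the short-minus-long difference register a
  crossing at the first opposite-signed nonzero bin.
* Marker sequences are unwrapped by anchoring each day to the running
  median of the last five unwrapped values. Anchoring to the immediately
  preceding day (the naive rule) lets one aberrant marker — e.g. a spurious
  balance crossing on a transition day — shift every subsequent day by a
  full cycle.
* Delay estimates default to LD days 2–7 as baseline (day 1 lacks a full
  24-h moving-average window) and the last 5 treatment days as steady
  state; which treatment days entered the published per-animal means is
  not stated, so the day sets are arguments.

The free-running period is 24 h plus the slope of unwrapped onsets against
day index, requiring at least 4 valid days.

## Sleep scoring

A 10-s bin is asleep iff it lies in a maximal run of zero-count bins of
length ≥ 4 (≥ 40 s of immobility). Summaries use 4-h bins; a bout is
assigned to the bin containing its onset for the duration statistic while
proportions count per-bin membership, keeping proportions exact and
durations interpretable. Bout durations are means per bin (medians are an
option; the published figures do not say which was used).

## Bioluminescence rhythms

Shutter-gated traces (1 closed minute per 15) are background-corrected by
linear interpolation between closed minutes — exact for backgrounds that
are piecewise linear between them, with linear extrapolation at the ends —
then block-averaged to 15-min resolution to stabilize Poisson noise.
The circadian component is the 16–32-h band of a maximal-overlap discrete
wavelet transform multiresolution analysis (Daubechies least-asymmetric
LA(8) filter, reflection boundary); the noise band for the signal-to-noise
ratio is < 4 h (detail levels 1–3 at 15-min sampling), giving dyadic bands
that bracket 24 h. The wavelet family is a package default, not a claim
about the original processing, which is not restated in the methods being
emulated.

The acrophase is the circular mean of per-cycle peak times of the
band-limited series rather than a single cosinor fit, because a
free-running period ≠ 24 h biases any fixed-period cosinor. Peaks are
refined by a local parabola (sub-bin resolution) and peaks within 12 h of
either end of the trace are discarded — the reflection boundary distorts
extrema inside that zone by up to ~2 h. The period estimate is 24 h plus
the slope of unwrapped per-cycle acrophases against cycle index, mirroring
the free-running-period estimator.

The continuous wavelet transform (analytic Morlet, center frequency 6,
evaluated in the Fourier domain) yields time-averaged power per period on
activity rebinned to 6 min, with the cone of influence excluded.

## Expression rhythms

Ct tables are normalized per sample as `dCt = Ct(target) - mean(Ct(hk1),
Ct(hk2))` — algebraically identical to dividing `2^-Ct` by the geometric
mean of the housekeeping `2^-Ct`, but computed on the Ct scale to avoid
underflow — then peak-normalized to `2^-ddCt` within each lighting
condition, so per-condition maxima are exactly 1 and amplitudes are *not*
comparable across conditions. Acrophases come from a 24-h single-harmonic
least-squares fit; the center of gravity of the fitted wave (circular mean
weighted by its positive part above the mesor) is reported as a
cross-check and coincides with the fitted acrophase for a single harmonic.
Whether the original center-of-gravity software weighted raw points or the
fitted wave is unknowable from the available description, so both values
are exposed. Four sampled time points cannot support a second harmonic;
one is available as an option but off by default. Fits whose zero-amplitude
F test has p > 0.3 are flagged unreliable. Phase shifts are wrapped to
(−12, 12] and pooled across tissues with a two-tailed one-sample t test.
Cells with 2–3 replicates are used as-is; nothing is imputed.

## Recognition memory and the window scan

The recognition ratio (novel / total exploration in the first 60 s of the
test phase — elapsed test time, not cumulative exploration time) is coupled
in the generator to the *true* preceding-2-h sleep proportion:
`ratio = clamp(beta0 + beta1 * S2h + b_i + e, 0, 1)` with defaults
`beta0 = 0.45`, `beta1 = 0.35`, random-intercept SD 0.06 and residual SD
0.10 — the calibrated preset under which the group-level 2-h window scan
reaches R² ≈ 0.9, the published asymptote. Exploration times are
back-filled from a log-normal total (median 20 s in the first minute) so
only the ratio carries signal; sample-phase exploration is independent of
sleep by construction, which the control models should (and do) report as
null.

The window scan computes prior-sleep proportions at widths 10–180 min in
10-min steps, averages ratio and sleep within the 8 lighting × ZT ×
stimulus cells, and records the R² of the cell-mean regression per width
(per-stimulus fits are also available; the default pools all 8 cells as in
the published figure). A quadratic trend of R² on width and a plateau
summary (R² at 120 min; smallest width reaching 95% of the maximum) are
attached.

The mixed model `ratio ~ sleep2h + (1 | mouse)` is fitted by maximum
likelihood (not REML, for deviance comparability); the sleep effect is the
likelihood-ratio χ² against the null without the fixed effect, and its
confidence interval is a percentile parametric bootstrap (simulate from
the fitted model, refit; default 2,000 iterations here, 10,000 reproduces
the full-length analysis). Undefined ratios (zero exploration) are
excluded listwise. Singular random-effect fits fall back to ordinary
regression with a flag.

## Problem sizes and reproducibility

The cohort presets use 12 animals × (7 d LD + 13 d DLE), two 8-animal DD
groups × 5 d, 8 + 8 five-day bioluminescence traces, 4 tissues × 4 ZTs ×
2 conditions × 4 replicates of qPCR, and 11 mice × 8 trials of
recognition — the sizes of the experiments being emulated. All generators
take a single integer seed; sub-generators derive child seeds by fixed
offsets, and a fixed seed reproduces every output bit-identically.
`run_experiment()` chains every stage from one master seed and emits a
summary JSON with recovered quantities next to their programmed truths.

## What the synthetic data do not emulate

The generator reproduces rate geometry, not physiology: there is no
sleep-homeostat or SCN model, no melatonin, no body-temperature coupling,
and sleep is whatever the immobility rule extracts from the two-state
count process. Count marginals are Poisson, whereas real PIR counts are
over-dispersed; re-entrainment is first-order with a single free constant;
and recognition ratios are linear in sleep with Gaussian noise, so
passing recovery tests demonstrates that the analysis chain measures what
it claims on data of known structure — not that the biological effect
sizes would be recovered from any particular real recording.
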