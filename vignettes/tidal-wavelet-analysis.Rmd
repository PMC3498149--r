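---
title: "Wavelet analysis of tidally driven plankton time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet analysis of tidally driven plankton time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidewave)
```

## The problem

Phytoplankton in shallow macrotidal seas fluctuate on the time scales of the
tide itself: the semidiurnal water-level cycle (12 h 25 min for the M2
constituent), the quarter-diurnal cycle of tidal current speed (6 h 12 min),
the fortnightly spring–neap cycle (~14.77 d, from M2–S2 interference) and
the ~27.6 d apogee–perigee cycle (M2–N2). High-frequency mooring records of
chlorophyll fluorescence, suspended particulate matter (SPM), salinity,
temperature, nitrate and irradiance make these periodicities measurable —
if the analysis chain handles gaps, sensor artefacts (daytime fluorescence
quenching), strong autocorrelation and non-stationarity.

`tidewave` implements that chain: preprocessing to relative rates of change,
the Morlet continuous wavelet transform (CWT) with red-noise significance,
segment-aggregated global spectra, and wavelet coherence with phase-angle
statistics. Because suitable public mooring telemetry cannot be assumed, the
package also ships a synthetic-data generator whose ground truth is known
exactly, so every stage of the chain is testable end to end.

## Preprocessing

Concentrations integrate the history of growth and loss; their *rate of
change* reflects conditions at the time of measurement. The transformation
is:

1. natural-log transform (suppresses isolated peaks, makes rates relative);
2. centred 3-point moving average of the log series (damps measurement
   noise without touching tidal periods);
3. first difference, `r_t = z_t − z_(t−1)` — on the log scale a relative
   rate of change ("relative growth rate" for chlorophyll).

Missingness is propagated, not renormalised: a smoothing window touching a
missing value yields a missing value. This is conservative and keeps the
segmentation logic simple; the alternative (renormalising partial windows)
would manufacture smoothed values at gap edges from one-sided information.

Averaging rules: hourly and daily bins require at least half of their
expected samples (our choice — it prevents a single stray reading from
standing in for an hour or day; the daily chlorophyll rule below is the
exception). Daily chlorophyll means use only *dark* samples (co-registered
PAR at 1 m < 1 µmol quanta m⁻² s⁻¹, strict inequality), because
non-photochemical quenching depresses daytime fluorescence; a single dark
sample qualifies a day, since dark samples are structurally a minority.
Gaps of exactly one sample are filled by linear interpolation; longer gaps
split the record. Gap-free segments enter the wavelet analysis only if they
exceed 100 consecutive hours (hourly cadence) or 60 consecutive days (daily
cadence) — strictly, so a run of exactly 100 hourly samples is rejected —
because a wavelet can only resolve periods up to roughly 25 % of a segment's
length.

Two small derived quantities round out preprocessing: the light attenuation
coefficient `Kd = ln(I₁/I₂)` per metre from PAR at 1 m and 2 m, and the
SPM-equivalent mass of the phytoplankton standing stock,
chlorophyll × 2.5 (biomass : carbon) × 40 (carbon : chlorophyll) = 100 mg
SPM-equivalent per mg chlorophyll.

## Tidal kinematics

The daily tidal range is `max − min` of each calendar day's water level; it
carries the spring–neap and apogee–perigee modulation. The tidal current
speed proxy is `TC = |ΔW/Δt|`: rectification folds the semidiurnal period
into a quarter-diurnal one, because currents peak twice per tide.

A deliberate convention choice: when TC is paired with an hourly
rate-of-change series in coherence analysis, TC is computed by differencing
the *hourly-averaged* water level rather than by hourly-averaging the
10-minute differences. A backward difference of hourly averages represents
time `t − 5 min` for *both* series, so their relative phase is unbiased;
differencing at 10-minute cadence first and averaging afterwards leaves TC
representing `t + 20 min` and injects a spurious ~25-minute lag (~24° at the
372-minute period) into every cross-phase estimate. Both paths are
available (`tidal_current_speed()` works at any cadence); the pipeline uses
the unbiased one.

## The Morlet transform and its conventions

The mother wavelet is `π^(−1/4)·exp(iω₀η)·exp(−η²/2)` with `ω₀ = 6`. The
transform is computed in the frequency domain over the dyadic scale grid
`s_j = s0·2^(j·dj)`, after removing the segment mean and zero-padding to the
next power of two. Fixed constants, with their standard values for `ω₀ = 6`:

* Fourier period `λ = 4πs/(ω₀ + √(2+ω₀²)) ≈ 1.033 s`;
* cone of influence (COI): e-folding distance `√2·s`, mapped to period
  units, rising linearly from each segment edge — cells above the COI are
  excluded from every statistic;
* reconstruction constant `C_δ = 0.776` (total power rebuilds the segment
  variance to within 5 % on smooth signals — tested);
* decorrelation constant `γ = 2.32` for time-averaged significance.

Defaults: `s0 = 2Δt`, `dj = 1/24`, scales spanning to ~25 % of the segment
length. `dj = 1/32` is used where the 24.000 h solar day must be separated
from the 24 h 50 min lunar day — at `dj = 1/24` the two differ by about
1.2 scale steps, uncomfortably close to the grid resolution.

**Power convention.** Un-rescaled power `|W|²` is stored and used for all
significance testing (the χ² null below is defined in that convention); a
scale-normalised view (`power/s`) is available for plotting only. One
consequence, worth knowing: in un-rescaled global spectra, equal-amplitude
components gain power with period, so broad-band comparisons across very
different scales should be made within the band of interest.

**Numerical caveat at the smallest scales.** At `s0 = 2Δt` the Morlet
centre frequency coincides with the Nyquist frequency; the spectral
daughter truncates above Nyquist while a sampled time-domain wavelet
aliases, so the two legitimately differ there. From `s ≥ 4Δt` the wavelet
is band-limited to ~10⁻¹⁰ and the FFT implementation matches brute-force
time-domain convolution to ~10⁻⁹ relative error (tested).

**Red-noise significance.** Environmental series are autocorrelated, so
power is tested against an AR(1) null with the series' own lag-1
autocorrelation α (clipped to [0, 0.999]). The null's normalised spectrum is
`P(f) = (1−α²)/(1+α²−2α·cos 2πf)`; the pointwise 95 % threshold is
`σ²·P·χ²₂(0.95)/2`. Calibration is verified by simulation: on white noise,
5 % ± 2 of cells outside the COI exceed the threshold.

**Global spectra across segments.** The global spectrum is the average of
local power over *all time points* of all segments, so longer segments
weigh proportionally more (the alternative — equal weight per segment —
would let a marginal 101-hour run count as much as a three-month run). Its
significance curve uses the time-averaged χ² approximation with
`dof = 2·√(1 + (nΔt/(γs))²)`. Peak periods are refined by parabolic
interpolation over (log₂ period, power), so they are not quantised to the
scale grid; ties break toward the shorter period, and a peak on a band
boundary is flagged rather than refined.

## Wavelet coherence and phase

Squared coherence is
`R² = |S(W_xy/s)|² / (S(|W_x|²/s)·S(|W_y|²/s))` with `W_xy = W_x·conj(W_y)`.
The smoothing operator `S` — without which R² ≡ 1 — is the standard one for
`ω₀ = 6`: in time, a Gaussian of standard deviation `s` (the wavelet's own
envelope), applied spectrally on a zero-padded grid; across scales, a
boxcar of 0.6 octaves (`0.6/dj` bins, edge-renormalised).

Phase convention: `φ = arg S(W_xy)`, positive when the first series leads;
0° is in-phase, reported on [0°, 360°). If x lags y by delay `L` at period
`P`, the reported phase is `360·(1 − L/P)`; `phase_to_lag()` inverts this.
A 316.5° phase at the 372-minute quarter-diurnal period is thus a ~45-minute
lag — and the paper-grade check in the test suite shows exactly this window
(310–330°) emerging from the simulator's 45-minute entrainment delay.

Coherence significance has no closed form, so it is Monte-Carlo: surrogate
pairs of independent AR(1) processes matched in length and lag-1
autocorrelation, per-scale 95 % quantiles of surrogate R² pooled over
surrogates and over time points outside the COI (a seeded, reproducible
procedure; ≥ 100 surrogates required, 300 by default). Time points are
subsampled (64 columns) when pooling: adjacent cells at one scale are
strongly dependent, so the subsample estimates the pooled quantile at a
fraction of the memory. Phase histograms (default 20° bins, matching the
granularity at which dominant windows like 310–330° are conventionally
reported) pool significant cells in a period band and return circular mean
and circular SD; whether to pool across all scales or one band is exposed
via the `band` argument.

## The synthetic generator: what it emulates

The generator is first-class code, not a fixture: its defaults define the
study conditions that every end-to-end test runs under.

* **Tide** — harmonic superposition of M2 (2.15 m, 745.236 min), S2
  (0.65 m, 720 min) and N2 (0.42 m, 759.5009 min): standard constituent
  periods; amplitudes chosen so the mean daily range is ≈ 4.3 m, typical of
  the outer Thames estuary. The spring–neap (14.77 d) and apogee–perigee
  (27.55 d) cycles are emergent beats, not separate inputs.
* **SPM** — resuspension–settling balance
  `S(t+Δ) = S(t) + Δ·[k_r·TC(t−45 min)² − k_s·(S − S_bg)]`, forced by the
  same `|ΔW/Δt|` proxy the analysis uses (consistency over hydrodynamic
  realism). The 45-minute entrainment delay is the time for renewed mixing
  to carry settled material back to the surface. `k_s = 0.1 h⁻¹` is chosen
  so that the phase lead of `dS/dt` over the forcing, `atan(k_s/ω)` ≈ 5.6°
  at the quarter-diurnal frequency, stays below one 10-minute sample —
  larger settling rates would bias the emergent chlorophyll–TC phase out of
  the observed window. Resuspension strength is modulated seasonally
  (±33 %, peaking mid-January) to emulate the winter wind-wave climate and
  reproduce the ~2× winter/summer SPM contrast of turbid temperate coastal
  water.
* **Chlorophyll fluorescence** — `(f·S + B)·(1 − q·daylight(t))`: a
  tychoplankton component riding on SPM, plus a pelagic pool `B` with
  Monod light-limited growth (light = surface irradiance attenuated by
  `exp(−k_d·S)`), a logistic ceiling standing in for nutrient limitation, a
  small constant seeding flux (the resting stock that lets spring blooms
  initiate after a winter of net loss), and AR(1) growth-rate process noise
  (σ = 0.2 d⁻¹, 2-day correlation) representing grazing and patchiness.
  `daylight(t)` is a clipped sinusoid with an *exactly* 24.000 h period and
  seasonal amplitude modulation, so quenching is distinguishable from the
  24 h 50 min lunar alternative.
* **Bloom window** — inside a configurable interval (default days 100–130,
  i.e. mid-April to mid-May of a 1 January start) resuspension is scaled by
  0.15: SPM collapses, light improves, `B` escapes. During the escape the
  chlorophyll 15-day band decouples from the tidal range because `B`'s
  process noise, amplified by the now-large `B`, dominates the small
  residual tidal component — the mechanism behind the tested strict
  inequality (significant coherence fraction inside < outside the window).
  A 30-day window holds only ~2 spring–neap cycles, so this fraction has
  high sampling variance across seeds; the tests pin the default seed.
* **Salinity / nitrate** — in phase / in anti-phase with water level at the
  semidiurnal period (horizontal advection of the estuarine gradient).
* **Temperature** — seasonal sinusoid plus a small semidiurnal advective
  term; deliberately *no* diel heating term.
* **Observation noise** — multiplicative lognormal AR(1) (α = 0.5,
  σ = 0.1), because the analysis log-transforms data and tests against red
  noise. Applied at full strength to the optical/chemical sensors, at
  σ/20 and σ/10 to salinity and temperature (a CT sensor's relative error
  is far smaller), and not at all to the tide gauge. `noise_sigma = 0` is
  the single switch that makes a run fully deterministic.

What the generator does *not* emulate: sensor drift and biofouling,
interannual variability, storm events, advective patchiness unrelated to
the tide, nutrient dynamics beyond a logistic ceiling, and any spatial
structure. Passing tests therefore demonstrate that the analysis recovers
known periodicities, phases and their disruptions under realistic noise and
gap structure — not that it would be robust to every artefact of field
telemetry.

## Problem sizes and degenerate inputs

The test suite and the acceptance script use 30–360-day records (10-minute
to daily cadence), 100–300 Monte-Carlo surrogates and 200-replicate
calibration loops; these sizes were chosen so each statistic's sampling
error is comfortably below the tolerance being asserted. Degenerate inputs
fail loudly and early: constant series (undefined autocorrelation), series
with non-positive values entering the log transform (reported with the
offending index), gappy segments reaching a transform, mismatched grids
entering coherence or global aggregation, and empty phase selections (a
warning and an `empty` flag, not an error, since an absence of significant
cells is a result).

## Known limitations

* The AR(1) null is fitted per segment; strongly periodic series push α̂
  toward 1, making the red-noise test conservative at long periods.
* Zero-padding damps power near segment edges; the COI accounts for the
  e-folding but a small bias remains just outside it.
* The Monte-Carlo coherence threshold assumes the two series' dependence
  is fully captured by their lag-1 autocorrelations.
* `peak_period()` refines a single maximum; closely spaced peaks within a
  band (e.g. M2 and S2 themselves, 1.2 scale steps apart at `dj = 1/24`)
  merge into one amplitude-weighted peak.
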