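# tidewave

Wavelet analysis of tidally driven coastal plankton time series.

## The problem

In shallow macrotidal seas, phytoplankton concentration fluctuates on the
time scales of the tide itself. High-frequency moorings record chlorophyll
fluorescence, suspended particulate matter (SPM), salinity, temperature,
nitrate, irradiance and water level at 10–30 minute cadence, and those
records carry a stack of superimposed periodicities:

| periodicity | origin |
|---|---|
| 6 h 12 min | tidal current speed (quarter-diurnal): resuspension and settling of particles — including tychoplanktonic algae — twice per tide |
| 12 h 25 min | semidiurnal (M2) horizontal displacement of water masses |
| 24 h sharp | the solar day: non-photochemical quenching of the fluorescence signal |
| ~14.77 d | spring–neap cycle (M2–S2 beat), modulating tidal range and mixing |
| ~27.6 d | apogee–perigee cycle (M2–N2 beat) |

`tidewave` is for ecologists and coastal oceanographers who want to
quantify these signals in mooring data: which periodicities are significant
against a red-noise null, how two series cohere, and what their phase
angles say about lead–lag mechanics (e.g. the ~45-minute delay between
tidal current speed and the chlorophyll rate of change that reflects the
time needed to mix settled cells back to the surface).

## What it computes

* **Preprocessing** — hourly/daily averaging (daily chlorophyll confined to
  dark samples, PAR < 1 µmol quanta m⁻² s⁻¹), single-sample gap
  interpolation, and the three-step transform to relative rates of change:
  `r_t = z_t − z_(t−1)` where `z` is the 3-point smoothed natural log.
  Records are split into gap-free segments (> 100 h hourly, > 60 d daily).
* **Tidal kinematics** — daily tidal range (max − min water level) and the
  tidal-current-speed proxy `TC = |ΔW/Δt|`.
* **Morlet CWT** (`ω₀ = 6`, scales `s_j = s0·2^(j·dj)`, Fourier period
  `λ ≈ 1.033 s`, cone of influence `√2·s`) with pointwise AR(1) red-noise
  significance: threshold `σ²·P(f)·χ²₂(0.95)/2` with
  `P(f) = (1−α²)/(1+α²−2α·cos 2πf)`.
* **Global wavelet spectra** aggregated across segments by time-point
  weighting, with time-averaged χ² significance and parabolic peak
  refinement.
* **Wavelet coherence**
  `R² = |S(W_xy/s)|² / (S(|W_x|²/s)·S(|W_y|²/s))`, Monte-Carlo AR(1)
  surrogate significance, and phase-angle histograms with circular
  statistics (positive phase = first series leads; a phase φ at period P
  maps to a lag `(360−φ)/360·P`).
* **A synthetic generator** — harmonic tide (M2/S2/N2), a
  resuspension–settling SPM model forced by TC² with a 45-minute
  entrainment delay, a light-limited pelagic chlorophyll pool with a
  spring-bloom "escape" window, solar-locked quenching, in-phase salinity /
  anti-phase nitrate, and seeded lognormal AR(1) observation noise — so the
  entire chain is verifiable against known ground truth.

## Worked example

Simulate two months of mooring data, transform chlorophyll to relative
rates of change, and ask how it relates to tidal current speed:

```r
library(tidewave)

tide <- generate_water_level(tide_config(duration = 60))
sim  <- generate_ecosystem(tide, ecosystem_params(seed = 1,
                                                  bloom_window = NULL))

chl  <- hourly_average(sim$chlorophyll)
rate <- log_smooth_diff(fill_small_gaps(chl))
seg  <- find_segments(rate, 101)[[1]]
rx   <- extract_segment(rate, seg)

gs <- global_spectrum(morlet_cwt(rx))
gs
#> <tw_gws> rate_chlorophyll: 179 periods (124-2.12e+04 min), 1437 time points, alpha 0.539
#>   peak period: 1438 min (24 h / 0.999 d)
peak_period(gs, band = c(300, 450)) / 60
#> [1] 6.199209
```

The overall peak sits at 24 h — the quenching artefact — and the
quarter-diurnal band peaks at 6.2 h, the tidal-mixing signal. Now the
phase relation with tidal current speed:

```r
tc  <- tidal_current_speed(hourly_average(sim$water_level))
off <- as.numeric(difftime(rx$start_time, tc$start_time, units = "mins")) / 60
ty  <- timeseries(tc$values[(off + 1):(off + length(rx$values))],
                  rx$start_time, 60, "tc")

coh <- mc_coherence_significance(rx, ty, wavelet_coherence(rx, ty),
                                 n_surrogates = 100, seed = 1)
ph  <- phase_distribution(coh, band = c(300, 450))
ph
#> <tw_phasehist> rate_chlorophyll ~ tc, band 300-450 min: 18521 angles, circular mean 320.0 deg (sd 15.4)
phase_to_lag(ph$circ_mean, 372.6)
#> [1] 41.3592
```

The significant phase angles cluster around 320°: the chlorophyll rate of
change fluctuates nearly in phase with tidal current speed, lagging it by
roughly 41 minutes — recovering (within noise) the 45-minute entrainment
delay the simulator was built with.

`run_pipeline(pipeline_config(...))` composes the whole sequence —
simulate/read, average, transform, segment, wavelet, coherence — and writes
every intermediate CSV plus a `summary.json` of peak periods and phase
statistics, stamped with the seed and a configuration hash.

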