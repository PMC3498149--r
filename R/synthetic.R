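#' Default semidiurnal tidal constituents
#'
#' Standard harmonic constituents of a macrotidal semidiurnal regime such as
#' the southern North Sea. M2 (principal lunar, 12 h 25.2 min) dominates; the
#' M2--S2 interference produces the ~14.77-day spring--neap cycle and the
#' M2--N2 interference the ~27.55-day apogee--perigee modulation. Amplitudes
#' are set so that the mean daily tidal range of the default mixture is about
#' 4.3 m, typical of the outer Thames estuary.
#'
#' @param names subset of `c("M2", "S2", "N2")` to include.
#' @return data.frame with columns `name`, `amplitude` (m), `period`
#'   (minutes) and `phase` (radians in `[0, 2*pi)`).
#' @examples
#' tidal_constituents()
#' beat_period(745.236, 720) / 1440   # spring-neap cycle, days
#' @export
tidal_constituents <- function(names = c("M2", "S2", "N2")) {
  all <- data.frame(
    name = c("M2", "S2", "N2"),
    amplitude = c(2.15, 0.65, 0.42),
    period = c(745.236, 720.000, 759.5009),
    phase = c(0, 0, 0))
  missing <- setdiff(names, all$name)
  if (length(missing)) stop("unknown constituent(s): ",
                            paste(missing, collapse = ", "))
  all[match(names, all$name), , drop = FALSE]
}

#' Beat period of two harmonic constituents
#'
#' Closed-form synodic period `1 / |1/p1 - 1/p2|` of the slow amplitude
#' modulation produced by two interfering harmonics: ~14.77 d for M2 + S2
#' (spring--neap) and ~27.55 d for M2 + N2 (apogee--perigee).
#'
#' @param p1,p2 constituent periods, in the same unit (e.g. minutes).
#' @return Beat period in the same unit.
#' @export
beat_period <- function(p1, p2) {
  stopifnot(p1 > 0, p2 > 0, p1 != p2)
  1 / abs(1 / p1 - 1 / p2)
}

#' Tide-generation configuration
#'
#' @param constituents data.frame as returned by [tidal_constituents()]
#'   (columns `name`, `amplitude`, `period`, `phase`).
#' @param start_time first sample timestamp (UTC).
#' @param duration length of the record in days.
#' @param sampling_interval sample spacing in minutes; must divide 60 so that
#'   hourly averaging is exact. Tide gauges typically record every 10 min.
#' @param mean_level mean water level in metres.
#' @return A list of class `tw_tideconfig`.
#' @export
tide_config <- function(constituents = tidal_constituents(),
                        start_time = "2007-01-01", duration = 360,
                        sampling_interval = 10, mean_level = 0) {
  if (!is.numeric(duration) || duration <= 0)
    stop("invalid tide config: `duration` must be positive (days)")
  if (60 %% sampling_interval != 0)
    stop("`sampling_interval` must divide 60 minutes")
  if (nrow(constituents) > 0) {
    stopifnot(all(constituents$amplitude >= 0), all(constituents$period > 0),
              all(constituents$phase >= 0 & constituents$phase < 2 * pi))
  }
  structure(list(constituents = constituents, start_time = as_utc(start_time),
                 duration = duration, sampling_interval = sampling_interval,
                 mean_level = mean_level),
            class = "tw_tideconfig")
}

#' Synthesise a tidal water-level record from harmonic constituents
#'
#' Deterministic superposition
#' `W(t) = mean_level + sum_i A_i * cos(2*pi*t/T_i + phi_i)`
#' evaluated on the configured grid. With the default M2 + S2 + N2 mixture
#' the record shows the 12 h 25 min semidiurnal oscillation, the ~15-day
#' spring--neap envelope and the ~28-day apogee--perigee modulation.
#'
#' @param config a [tide_config()] object.
#' @return A `tw_ts` water-level series in metres.
#' @export
generate_water_level <- function(config) {
  stopifnot(inherits(config, "tw_tideconfig"))
  n <- round(config$duration * 1440 / config$sampling_interval)
  if (n < 1) stop("invalid tide config: empty sampling grid")
  t_min <- (seq_len(n) - 1) * config$sampling_interval
  w <- rep(config$mean_level, n)
  cc <- config$constituents
  if (nrow(cc) > 0) {
    for (i in seq_len(nrow(cc)))
      w <- w + cc$amplitude[i] * cos(2 * pi * t_min / cc$period[i] +
                                       cc$phase[i])
  }
  timeseries(w, config$start_time, config$sampling_interval,
             variable = "water_level", units = "m")
}

#' Ecosystem simulation parameters
#'
#' Tunable constants of the minimal resuspension--settling--growth model used
#' by [generate_ecosystem()]. The paper-grade mechanism is: tidal currents
#' resuspend bottom material (SPM and tychoplanktonic algae) with a short
#' entrainment delay; particles settle back towards a background
#' concentration during slack water; a pelagic growth pool responds to light,
#' which is attenuated by SPM turbidity; daytime non-photochemical quenching
#' depresses the fluorescence *signal* (not the biomass) on an exact 24 h
#' cycle. The rate constants are tuning constants, not field measurements,
#' and are recorded in the dataset's `truth` element.
#'
#' @param resuspension_coeff SPM source strength, mg L-1 per (m h-1)^2 per h.
#' @param seasonal_resuspension_amplitude relative annual modulation of the
#'   resuspension strength (peak in mid-January), emulating the winter
#'   wind-wave climate; 0.33 roughly reproduces the ~2x winter/summer SPM
#'   contrast of turbid temperate coastal waters.
#' @param settling_rate first-order settling towards background, h-1.
#' @param spm_background non-resuspendable SPM floor, mg L-1.
#' @param entrainment_delay lag between tidal current speed and the
#'   resuspension source, minutes.
#' @param chl_spm_fraction fluorescence-equivalent chlorophyll carried per
#'   unit resuspended SPM, mg m-3 per mg L-1.
#' @param growth_rate_max maximum specific growth rate of the pelagic pool,
#'   d-1 (diatom-typical).
#' @param light_half_saturation half-saturation irradiance, umol quanta
#'   m-2 s-1.
#' @param kd_per_spm light attenuation per unit SPM, m-1 per mg L-1.
#' @param quench_amplitude fractional midday depression of fluorescence in
#'   `[0, 1)`.
#' @param bloom_window two-element numeric (days since start) during which
#'   resuspension is scaled by `bloom_resuspension_factor`, emulating the
#'   neap-tide SPM collapse that lets the spring bloom escape the tidal
#'   regime; `NULL` disables it.
#' @param bloom_resuspension_factor multiplier on `resuspension_coeff` inside
#'   the bloom window.
#' @param salinity_tide_amplitude semidiurnal salinity excursion (psu) per
#'   full tidal amplitude, in phase with water level.
#' @param nitrate_tide_amplitude semidiurnal nitrate excursion (mmol m-3),
#'   in anti-phase with water level.
#' @param noise_ar1_alpha lag-1 autocorrelation of the multiplicative
#'   lognormal observation noise, in `[0, 1)`.
#' @param noise_sigma relative standard deviation of the observation noise;
#'   0 switches off every stochastic component (observation and growth
#'   noise), making the run fully deterministic.
#' @param growth_noise_sigma standard deviation (d-1) of the AR(1)
#'   process noise on the net growth rate of the pelagic pool, with a
#'   2-day correlation time. Represents growth variability from grazing,
#'   succession and patchiness; it is what decouples bloom chlorophyll
#'   from the tidal regime. Active only when `noise_sigma > 0`.
#' @param seed integer seed for the noise streams.
#' @param par_surface clear-sky midday surface irradiance, umol quanta
#'   m-2 s-1.
#' @param initial_biomass initial pelagic chlorophyll pool, mg m-3.
#' @param seeding_rate constant source to the pelagic pool, mg m-3 d-1;
#'   a resting-stock/advective seed that keeps winter biomass at a small
#'   positive floor so the spring bloom can initiate.
#' @param carrying_capacity logistic ceiling of the pelagic pool, mg m-3;
#'   stands in for the nutrient limitation that caps real spring blooms.
#' @param loss_rate specific loss rate of the pelagic pool, d-1.
#' @param temp_mean,temp_seasonal_amplitude annual mean and amplitude of
#'   water temperature, degrees C.
#' @param salinity_mean,nitrate_mean mean salinity (psu) and nitrate
#'   (mmol m-3).
#' @return A list of class `tw_ecoparams`.
#' @export
ecosystem_params <- function(resuspension_coeff = 3.5, settling_rate = 0.1,
                             seasonal_resuspension_amplitude = 0.33,
                             spm_background = 5, entrainment_delay = 45,
                             chl_spm_fraction = 0.1, growth_rate_max = 1.2,
                             light_half_saturation = 50, kd_per_spm = 0.1,
                             quench_amplitude = 0.3,
                             bloom_window = c(100, 130),
                             bloom_resuspension_factor = 0.15,
                             salinity_tide_amplitude = 0.15,
                             nitrate_tide_amplitude = 1,
                             noise_ar1_alpha = 0.5, noise_sigma = 0.1,
                             growth_noise_sigma = 0.2,
                             seed = 1L, par_surface = 1200,
                             initial_biomass = 0.5, seeding_rate = 0.01, loss_rate = 0.3,
                             carrying_capacity = 25,
                             temp_mean = 12.35, temp_seasonal_amplitude = 6.25,
                             salinity_mean = 34, nitrate_mean = 8) {
  if (settling_rate <= 0) stop("`settling_rate` must be positive")
  if (quench_amplitude < 0 || quench_amplitude >= 1)
    stop("`quench_amplitude` must lie in [0, 1)")
  if (noise_ar1_alpha < 0 || noise_ar1_alpha >= 1)
    stop("`noise_ar1_alpha` must lie in [0, 1)")
  p <- as.list(environment())
  structure(p, class = "tw_ecoparams")
}

# stationary AR(1) innovations with unit marginal variance
ar1_noise <- function(n, alpha) {
  e <- numeric(n)
  e[1L] <- stats::rnorm(1L)
  if (n > 1L) {
    innov <- stats::rnorm(n - 1L, sd = sqrt(1 - alpha^2))
    for (i in 2:n) e[i] <- alpha * e[i - 1L] + innov[i - 1L]
  }
  e
}

# clipped-sinusoid daylight factor in [0, 1], exact 24.000 h period with
# seasonal amplitude modulation (northern mid-latitudes, peak near the
# June solstice)
daylight_factor <- function(stamps) {
  hod <- as.numeric(format(stamps, "%H")) +
    as.numeric(format(stamps, "%M")) / 60
  doy <- as.numeric(format(stamps, "%j"))
  d <- pmax(0, sin(2 * pi * (hod - 6) / 24)) *
    (1 + 0.3 * cos(2 * pi * (doy - 172) / 365.25))
  pmin(d, 1)
}

#' Simulate co-varying mooring series from a tidal water level
#'
#' Drives a minimal sediment--plankton model with the tidal-current-speed
#' proxy `TC = |dW/dt|` computed from the supplied water level:
#'
#' * SPM obeys `S(t+dt) = S(t) + dt * (k_r * TC(t - delay)^2 -
#'   k_s * (S - S_bg))`, so it fluctuates in phase with tidal current speed
#'   at the quarter-diurnal (6 h 12 min) period and, under a multi-constituent
#'   tide, with tidal range at the spring--neap period.
#' * A pelagic chlorophyll pool `B` grows at
#'   `growth_rate_max * L / (L + K) - loss_rate`, where `L` is surface
#'   irradiance attenuated by `exp(-kd_per_spm * S)`; inside `bloom_window`
#'   resuspension is damped so SPM declines, light improves and `B` escapes.
#' * Observed chlorophyll fluorescence is
#'   `(chl_spm_fraction * S + B) * (1 - quench_amplitude * daylight(t))` —
#'   a solar-locked, exactly 24 h artefact of non-photochemical quenching.
#' * Salinity varies in phase, and nitrate in anti-phase, with water level
#'   at the semidiurnal period.
#' * Temperature is a seasonal sinusoid plus a small semidiurnal advective
#'   term; there is no diel heating term.
#' * Multiplicative lognormal AR(1) observation noise
#'   (`value * exp(sigma * e_t)`) is applied per sensor, reproducibly from
#'   `seed`; the tide gauge is left noise-free.
#'
#' @param tide a gap-free `tw_ts` water level (simulate before injecting
#'   gaps).
#' @param params an [ecosystem_params()] object.
#' @return A `tw_dataset`: co-registered `tw_ts` members `water_level`,
#'   `chlorophyll`, `spm`, `salinity`, `temperature`, `nitrate`, `par`, plus
#'   a `truth` record of every generating parameter.
#' @examples
#' tide <- generate_water_level(tide_config(duration = 20))
#' sim <- generate_ecosystem(tide, ecosystem_params(noise_sigma = 0))
#' sim
#' @export
generate_ecosystem <- function(tide, params = ecosystem_params()) {
  stopifnot(inherits(tide, "tw_ts"), inherits(params, "tw_ecoparams"))
  if (anyNA(tide$values))
    stop("tide must be gap-free: simulate first, inject gaps afterwards")
  w <- tide$values
  n <- length(w)
  step_h <- tide$step / 60
  step_d <- step_h / 24
  stamps <- ts_timestamps(tide)

  # tidal current speed proxy at the gauge cadence, backfilled at t = 0
  tc <- c(NA_real_, abs(diff(w)) / step_h)
  tc[1L] <- tc[2L]
  dlag <- round(params$entrainment_delay / tide$step)
  tc_lag <- if (dlag > 0) c(rep(tc[1L], dlag), tc[seq_len(n - dlag)]) else tc

  # bloom window: resuspension damped, SPM collapses, growth pool escapes
  day_from_start <- ts_minutes(tide) / 1440
  doy0 <- as.numeric(format(stamps, "%j"))
  bf <- 1 + params$seasonal_resuspension_amplitude *
    cos(2 * pi * (doy0 - 15) / 365.25)
  if (!is.null(params$bloom_window)) {
    inwin <- day_from_start >= params$bloom_window[1L] &
      day_from_start <= params$bloom_window[2L]
    bf[inwin] <- bf[inwin] * params$bloom_resuspension_factor
  }

  dl <- daylight_factor(stamps)
  i0 <- params$par_surface * dl

  # stochastic components: one master switch (noise_sigma > 0), one seed
  gnoise <- rep(0, n)
  if (params$noise_sigma > 0) {
    set.seed(params$seed)
    if (params$growth_noise_sigma > 0)
      gnoise <- params$growth_noise_sigma *
        ar1_noise(n, exp(-step_d / 2))   # 2-day correlation time
  }

  s <- numeric(n)
  b <- numeric(n)
  s[1L] <- params$spm_background +
    params$resuspension_coeff * bf[1L] * mean(tc^2) / params$settling_rate
  b[1L] <- params$initial_biomass
  kr <- params$resuspension_coeff
  ks <- params$settling_rate
  for (i in seq_len(n - 1L)) {
    s[i + 1L] <- max(0, s[i] + step_h *
                       (kr * bf[i] * tc_lag[i]^2 -
                          ks * (s[i] - params$spm_background)))
    l <- i0[i] * exp(-params$kd_per_spm * s[i])
    b[i + 1L] <- max(0, b[i] + step_d *
                       (b[i] * (params$growth_rate_max * l /
                                  (l + params$light_half_saturation) *
                                  (1 - b[i] / params$carrying_capacity) -
                                  params$loss_rate + gnoise[i]) +
                          params$seeding_rate))
  }

  par1m <- i0 * exp(-params$kd_per_spm * s)     # PAR at 1 m depth
  fl <- (params$chl_spm_fraction * s + b) * (1 - params$quench_amplitude * dl)
  wdev <- (w - mean(w)) / max(1e-12, max(abs(w - mean(w))))
  sal <- params$salinity_mean + params$salinity_tide_amplitude * wdev
  nit <- pmax(0, params$nitrate_mean - params$nitrate_tide_amplitude * wdev)
  doy <- as.numeric(format(stamps, "%j"))
  tem <- params$temp_mean +
    params$temp_seasonal_amplitude * cos(2 * pi * (doy - 202) / 365.25) +
    0.15 * (w - mean(w))

  if (params$noise_sigma > 0) {
    a <- params$noise_ar1_alpha
    sg <- params$noise_sigma
    # sensor-specific relative error: full for optical/chemical sensors,
    # much smaller for the CT sensor
    fl <- fl * exp(sg * ar1_noise(n, a))
    s <- s * exp(sg * ar1_noise(n, a))
    nit <- nit * exp(sg * ar1_noise(n, a))
    par1m <- par1m * exp(sg * ar1_noise(n, a))
    sal <- sal * exp(sg / 20 * ar1_noise(n, a))
    tem <- tem * exp(sg / 10 * ar1_noise(n, a))
  }

  mk <- function(v, var, un)
    timeseries(v, tide$start_time, tide$step, variable = var, units = un)
  truth <- params
  class(truth) <- "list"
  truth$constituent_note <- "see tide generation config"
  structure(list(
    water_level = mk(w, "water_level", "m"),
    chlorophyll = mk(fl, "chlorophyll", "mg m-3"),
    spm = mk(s, "spm", "mg L-1"),
    salinity = mk(sal, "salinity", "psu"),
    temperature = mk(tem, "temperature", "degC"),
    nitrate = mk(nit, "nitrate", "mmol m-3"),
    par = mk(par1m, "par", "umol m-2 s-1"),
    truth = truth), class = "tw_dataset")
}

#' @export
print.tw_dataset <- function(x, ...) {
  cat("<tw_dataset> synthetic mooring bundle\n")
  for (nm in setdiff(names(x), "truth")) print(x[[nm]])
  invisible(x)
}

#' Inject seeded gaps into a series
#'
#' Emulates the sensor outages of real mooring records: the requested runs of
#' samples are set to missing at random, non-overlapping positions. The input
#' is not modified.
#'
#' @param series a `tw_ts` object.
#' @param gap_lengths integer vector of gap lengths in samples (may be
#'   empty).
#' @param seed integer seed making the gap positions reproducible.
#' @return A copy of `series` with the gaps applied.
#' @export
inject_gaps <- function(series, gap_lengths, seed = 1L) {
  stopifnot(inherits(series, "tw_ts"))
  gap_lengths <- as.integer(gap_lengths)
  n <- length(series$values)
  if (length(gap_lengths) == 0L) return(series)
  if (any(gap_lengths < 1L)) stop("gap lengths must be positive")
  if (any(gap_lengths > n)) stop("gap longer than the series")
  if (sum(gap_lengths) >= n) stop("total gap length must be < series length")
  set.seed(seed)
  occupied <- rep(FALSE, n)
  for (g in sort(gap_lengths, decreasing = TRUE)) {
    placed <- FALSE
    for (attempt in seq_len(10000L)) {
      start <- sample.int(n - g + 1L, 1L)
      idx <- start:(start + g - 1L)
      if (!any(occupied[idx])) {
        occupied[idx] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place gaps without overlap")
  }
  out <- series
  out$values[occupied] <- NA_real_
  out
}

#' Write a synthetic dataset to a directory of CSV files
#'
#' One [write_timeseries()] CSV per variable plus a `truth.json` sidecar with
#' every generating parameter, so recovery tests can compare analysis output
#' against ground truth.
#'
#' @param dataset a `tw_dataset` from [generate_ecosystem()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tw_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in setdiff(names(dataset), "truth"))
    write_timeseries(dataset[[nm]], file.path(dir, paste0(nm, ".csv")))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
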