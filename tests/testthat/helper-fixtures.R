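# shared fixtures, built in code

# a sinusoid series: period in minutes, n samples at `step` minutes
sinusoid_ts <- function(period, n, step = 60, amplitude = 1, phase = 0,
                        start = "2007-01-01", variable = "x") {
  t_min <- (seq_len(n) - 1) * step
  timeseries(amplitude * cos(2 * pi * t_min / period + phase), start, step,
             variable = variable)
}

# two-constituent (M2 + S2) tide, the workhorse synthetic record
m2s2_tide <- function(duration, start = "2007-01-01") {
  generate_water_level(tide_config(
    constituents = tidal_constituents(c("M2", "S2")),
    duration = duration, start_time = start))
}

M2_PERIOD <- tidal_constituents("M2")$period   # 745.236 min
QUARTER_DIURNAL <- M2_PERIOD / 2               # 372.6 min

# simple AR(1) draw used as an independent noise source in tests
ar1_sim <- function(n, alpha, sd = 1) {
  as.numeric(stats::arima.sim(list(ar = alpha), n,
                              sd = sd * sqrt(1 - alpha^2)))
}

# trim a series to the grid of another (same step assumed), for pairing a
# rate-of-change segment with an untransformed forcing series
align_to <- function(donor, target) {
  off <- as.numeric(difftime(target$start_time, donor$start_time,
                             units = "mins")) / donor$step
  timeseries(donor$values[(off + 1):(off + length(target$values))],
             target$start_time, donor$step, variable = donor$variable)
}

# chlorophyll rate-of-change vs TC coherence on a simulated winter month;
# used by the phase-convention checks
chl_tc_coherence <- function(seed, n_surrogates = 100) {
  tide <- generate_water_level(tide_config(duration = 30))
  sim <- generate_ecosystem(tide, ecosystem_params(seed = seed,
                                                   bloom_window = NULL))
  rate <- log_smooth_diff(fill_small_gaps(hourly_average(sim$chlorophyll)))
  tc <- tidal_current_speed(hourly_average(sim$water_level))
  seg <- find_segments(rate, 101)[[1L]]
  rx <- extract_segment(rate, seg)
  ty <- align_to(tc, rx)
  coh <- wavelet_coherence(rx, ty)
  mc_coherence_significance(rx, ty, coh, n_surrogates = n_surrogates,
                            seed = seed)
}
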