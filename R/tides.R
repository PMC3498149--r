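#' Daily tidal range
#'
#' The tidal range of each calendar day is the difference between the
#' maximum and minimum water level of that day. Its slow modulation tracks
#' the spring--neap (~15 d) and apogee--perigee (~28 d) cycles. Days covered
#' by fewer than half of the expected water-level samples are missing. The
#' result is invariant under adding any constant to the water level.
#'
#' @param water_level a `tw_ts` of water level at sub-hourly cadence.
#' @return A daily `tw_ts` of tidal range in metres.
#' @export
tidal_range <- function(water_level) {
  stopifnot(inherits(water_level, "tw_ts"))
  if (water_level$step > 60)
    stop("tidal range needs sub-hourly water-level data")
  idx <- bin_index(water_level, 1440)
  ok <- !is.na(water_level$values)
  expected <- 1440 / water_level$step
  nbin <- max(idx) + 1L
  out <- rep(NA_real_, nbin)
  if (any(ok)) {
    rng <- tapply(water_level$values[ok], idx[ok],
                  function(v) max(v) - min(v))
    cnt <- tapply(rep(1, sum(ok)), idx[ok], sum)
    at <- as.integer(names(rng)) + 1L
    keep <- cnt >= expected / 2
    out[at[keep]] <- rng[keep]
  }
  timeseries(out, bin_start_time(water_level, 1440), 1440,
             variable = "tidal_range", units = "m")
}

#' Tidal-current-speed proxy
#'
#' The rate at which the water level rises or falls, `TC_t =
#' |W_t - W_(t-1)| / dt` in metres per hour, is a simple proxy of the tidal
#' current speed at a mooring without a current meter. Taking the absolute
#' value folds the 12 h 25 min semidiurnal periodicity of the water level
#' into a 6 h 12 min quarter-diurnal periodicity of TC: currents peak twice
#' per tide, between each high and low water. TC is independent of the
#' water-level datum.
#'
#' @param water_level a uniformly sampled `tw_ts` with at least 2 samples.
#' @return A `tw_ts` of TC in m h-1, one sample shorter than the input;
#'   missing where either water-level sample is missing.
#' @export
tidal_current_speed <- function(water_level) {
  stopifnot(inherits(water_level, "tw_ts"))
  w <- water_level$values
  if (length(w) < 2L) stop("need at least two water-level samples")
  tc <- abs(w[-1L] - w[-length(w)]) / (water_level$step / 60)
  timeseries(tc, water_level$start_time + water_level$step * 60,
             water_level$step, variable = "tc", units = "m h-1")
}
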