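# bin indices of each sample relative to the first bin; width in minutes
bin_index <- function(x, width) {
  origin <- trunc(as.numeric(ts_timestamps(x)[1L]) / (width * 60)) *
    (width * 60)
  floor((as.numeric(ts_timestamps(x)) - origin) / (width * 60))
}

bin_start_time <- function(x, width) {
  as.POSIXct(trunc(as.numeric(ts_timestamps(x)[1L]) / (width * 60)) *
               (width * 60), origin = "1970-01-01", tz = "UTC")
}

# mean per bin subject to a minimum-coverage rule
bin_average <- function(x, width, qualify = !is.na(x$values),
                        min_count = NULL) {
  idx <- bin_index(x, width)
  nbin <- max(idx) + 1L
  ok <- qualify & !is.na(x$values)
  tap <- tapply(x$values[ok], idx[ok], mean)
  cnt <- tapply(rep(1, sum(ok)), idx[ok], sum)
  out <- rep(NA_real_, nbin)
  if (length(tap)) {
    at <- as.integer(names(tap)) + 1L
    keep <- if (is.null(min_count)) rep(TRUE, length(at)) else cnt >= min_count
    out[at[keep]] <- tap[keep]
  }
  timeseries(out, bin_start_time(x, width), step = width,
             variable = x$variable, units = x$units)
}

#' Average a high-frequency series to one sample per clock hour
#'
#' Instrument cadences on moorings differ between sensors and deployments;
#' averaging to the clock hour yields a uniform dataset. Each hour is the
#' arithmetic mean of its non-missing samples; an hour covered by fewer than
#' half of its expected samples is marked missing, so a stray single reading
#' cannot stand in for a whole hour.
#'
#' @param raw a `tw_ts` with `step <= 60` dividing 60.
#' @return An hourly `tw_ts`.
#' @export
hourly_average <- function(raw) {
  stopifnot(inherits(raw, "tw_ts"))
  if (raw$step > 60) stop("cannot hourly-average a series coarser than 1 h")
  if (60 %% raw$step != 0) stop("sampling interval must divide 60 minutes")
  expected <- 60 / raw$step
  bin_average(raw, 60, min_count = expected / 2)
}

#' Average a series to one sample per calendar day
#'
#' For every variable except chlorophyll, a day is the mean of its
#' non-missing samples, missing when fewer than half of the expected samples
#' are present. Chlorophyll fluorescence is quenched under high light, so its
#' daily mean is confined to dark measurements: samples where the
#' co-registered PAR at 1 m depth is strictly below `dark_threshold`
#' (1 umol quanta m-2 s-1 by default); a day with no dark sample is missing.
#'
#' @param raw a `tw_ts` with sub-daily cadence.
#' @param par co-registered PAR series, required when
#'   `raw$variable == "chlorophyll"`.
#' @param dark_threshold irradiance below which a sample counts as dark.
#' @return A daily `tw_ts`.
#' @export
daily_average <- function(raw, par = NULL, dark_threshold = 1) {
  stopifnot(inherits(raw, "tw_ts"))
  if (raw$step > 1440) stop("cannot daily-average a series coarser than 1 d")
  if (identical(raw$variable, "chlorophyll")) {
    if (is.null(par))
      stop("daily chlorophyll averaging needs a co-registered PAR series")
    check_coregistered(raw, par)
    dark <- !is.na(par$values) & par$values < dark_threshold
    bin_average(raw, 1440, qualify = dark, min_count = 1)
  } else {
    expected <- 1440 / raw$step
    bin_average(raw, 1440, min_count = expected / 2)
  }
}

#' Fill isolated single-sample gaps by linear interpolation
#'
#' Only gaps of exactly one sample are filled (with the mean of the two
#' neighbours); longer gaps cannot be interpolated without affecting the
#' spectral content and are left untouched, as are missing samples at the
#' series ends. Non-missing values are never altered.
#'
#' @param series a `tw_ts`.
#' @return A copy with isolated gaps filled.
#' @export
fill_small_gaps <- function(series) {
  stopifnot(inherits(series, "tw_ts"))
  v <- series$values
  n <- length(v)
  if (n < 3L) return(series)
  i <- 2:(n - 1L)
  fix <- i[is.na(v[i]) & !is.na(v[i - 1L]) & !is.na(v[i + 1L])]
  out <- series
  out$values[fix] <- (v[fix - 1L] + v[fix + 1L]) / 2
  out
}

#' Transform concentrations to relative rates of change
#'
#' The three-step transformation applied to chlorophyll, SPM, salinity and
#' temperature before wavelet analysis: (1) natural-log transform, which
#' suppresses isolated large peaks; (2) a centred 3-point moving average of
#' the log series, damping measurement noise and patchiness without removing
#' tidal periodicities; (3) first differencing, `r_t = z_t - z_(t-1)`. On a
#' log scale the difference is a relative ("per step") rate of change — for
#' phytoplankton, a relative growth rate. Smoothing propagates missingness: a
#' window touching a missing value, or a series end, yields a missing sample.
#'
#' @param series a `tw_ts` whose non-missing values are all positive.
#' @return A `tw_ts` one sample shorter, with `transformed = TRUE` and unit
#'   "per step".
#' @examples
#' x <- timeseries(exp(0.1 * (0:20)), "2007-01-01", 60, "chlorophyll")
#' r <- log_smooth_diff(x)
#' range(r$values, na.rm = TRUE)   # exactly 0.1 in the interior
#' @export
log_smooth_diff <- function(series) {
  stopifnot(inherits(series, "tw_ts"))
  v <- series$values
  bad <- which(!is.na(v) & v <= 0)
  if (length(bad))
    stop("log transform needs positive values; first offending index: ",
         bad[1L])
  n <- length(v)
  if (n < 2L) stop("series too short to difference")
  y <- log(v)
  z <- rep(NA_real_, n)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    z[i] <- (y[i - 1L] + y[i] + y[i + 1L]) / 3
  }
  r <- z[-1L] - z[-n]
  timeseries(r, series$start_time + series$step * 60, series$step,
             variable = paste0("rate_", series$variable), units = "per step",
             transformed = TRUE)
}

#' Maximal gap-free segments long enough for wavelet analysis
#'
#' Wavelet analysis can only resolve periodicities up to about a quarter of a
#' record's length, so short gap-free stretches carry no usable information
#' at the periods of interest. This returns every maximal run of consecutive
#' non-missing samples whose length is at least `min_length`; conventional
#' thresholds are 101 hourly samples (strictly more than 100 consecutive
#' hours) and 61 daily samples (strictly more than 60 consecutive days).
#'
#' @param series a `tw_ts`.
#' @param min_length minimum run length in samples.
#' @return A list of segments, each `list(start_index, length)`, in order.
#' @seealso [extract_segment()]
#' @export
find_segments <- function(series, min_length) {
  stopifnot(inherits(series, "tw_ts"), min_length >= 1)
  r <- rle(!is.na(series$values))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  mapply(function(s, l) list(start_index = s, length = l),
         starts[keep], r$lengths[keep], SIMPLIFY = FALSE)
}

#' Extract one segment of a series as a gap-free `tw_ts`
#'
#' @param series a `tw_ts`.
#' @param seg one element of the list returned by [find_segments()].
#' @return A `tw_ts` covering only the segment.
#' @export
extract_segment <- function(series, seg) {
  idx <- seg$start_index:(seg$start_index + seg$length - 1L)
  timeseries(series$values[idx],
             series$start_time + (seg$start_index - 1L) * series$step * 60,
             series$step, variable = series$variable, units = series$units,
             transformed = series$transformed)
}

#' Light attenuation coefficient from PAR at two depths
#'
#' Beer--Lambert attenuation between the 1 m and 2 m sensors:
#' `Kd(t) = ln(I1 / I2) / (2 - 1)` per metre. Samples with non-positive
#' irradiance at either depth (night) are returned as missing.
#'
#' @param par_1m,par_2m co-registered irradiance series at 1 m and 2 m depth.
#' @return A `tw_ts` of Kd in m-1.
#' @export
kd_from_par <- function(par_1m, par_2m) {
  check_coregistered(par_1m, par_2m)
  i1 <- par_1m$values
  i2 <- par_2m$values
  kd <- ifelse(!is.na(i1) & !is.na(i2) & i1 > 0 & i2 > 0,
               log(i1 / i2), NA_real_)
  timeseries(kd, par_1m$start_time, par_1m$step, variable = "kd",
             units = "m-1")
}

#' SPM-equivalent mass of the phytoplankton standing stock
#'
#' Converts a chlorophyll concentration to the dry mass it contributes to
#' suspended particulate matter, via a phytoplankton biomass-to-carbon ratio
#' (default 2.5) and a carbon-to-chlorophyll ratio (default 40, typical of
#' marine diatoms in nutrient-rich temperate waters): 1 mg m-3 of
#' chlorophyll then contributes 100 mg m-3 of SPM.
#'
#' @param chlorophyll chlorophyll concentration(s), mg m-3.
#' @param biomass_carbon_ratio dry mass per unit carbon, dimensionless.
#' @param carbon_chl_ratio carbon per unit chlorophyll, dimensionless.
#' @return SPM-equivalent concentration, mg m-3.
#' @export
chl_spm_contribution <- function(chlorophyll, biomass_carbon_ratio = 2.5,
                                 carbon_chl_ratio = 40) {
  if (any(chlorophyll < 0, na.rm = TRUE) || biomass_carbon_ratio < 0 ||
      carbon_chl_ratio < 0)
    stop("all arguments must be non-negative")
  chlorophyll * biomass_carbon_ratio * carbon_chl_ratio
}
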