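test_that("hourly averaging reduces cadence and applies the coverage rule", {
  # constant series stays constant
  x <- timeseries(rep(3, 36), "2007-01-01", 10)
  h <- hourly_average(x)
  expect_equal(h$values, rep(3, 6))
  expect_equal(h$step, 60)
  # two-point mean at 30-min cadence
  x2 <- timeseries(c(1, 3), "2007-01-01", 30)
  expect_equal(hourly_average(x2)$values, 2)
  # an hour with less than half coverage is missing
  x3 <- timeseries(c(1, NA, NA, NA, NA, NA), "2007-01-01", 10)
  expect_true(is.na(hourly_average(x3)$values[1]))
  expect_error(hourly_average(timeseries(1:3, "2007-01-01", 90)), "coarser")
})

test_that("hourly means tolerate one missing sample per hour", {
  # 12-min cadence sinusoid with one sample knocked out per hour
  t_min <- (0:59) * 12
  v <- sin(2 * pi * t_min / 745.236)
  x_full <- timeseries(v, "2007-01-01", 12)
  v[seq(3, 60, by = 5)] <- NA   # third slot of every hour
  x_gappy <- timeseries(v, "2007-01-01", 12)
  full <- hourly_average(x_full)$values
  gappy <- hourly_average(x_gappy)$values
  # explicit enumeration oracle for the degraded means
  oracle <- vapply(0:11, function(h) {
    idx <- which(t_min >= h * 60 & t_min < (h + 1) * 60)
    mean(v[idx], na.rm = TRUE)
  }, 0)
  expect_equal(gappy, oracle)
  expect_true(all(abs(gappy - full) < 0.05))
})

test_that("daily chlorophyll means use dark samples only", {
  # chlorophyll: 10 at night, quenched 5 by day; PAR >= 1 exactly when quenched
  n <- 48
  par_v <- rep(c(rep(0, 12), rep(100, 12)), 2)
  chl_v <- ifelse(par_v >= 1, 5, 10)
  chl <- timeseries(chl_v, "2007-01-01", 60, variable = "chlorophyll")
  par <- timeseries(par_v, "2007-01-01", 60, variable = "par")
  d <- daily_average(chl, par = par)
  expect_equal(d$values, c(10, 10))
  # all-light day is missing
  par2 <- timeseries(rep(100, n), "2007-01-01", 60, variable = "par")
  expect_true(all(is.na(daily_average(chl, par = par2)$values)))
  # chlorophyll without PAR is an error; other variables need none
  expect_error(daily_average(chl), "PAR")
  x <- timeseries(rep(7, n), "2007-01-01", 60, variable = "spm")
  expect_equal(daily_average(x)$values, c(7, 7))
})

test_that("averaging is idempotent on already-averaged input", {
  x <- timeseries(rnorm(240), "2007-01-01", 60)
  expect_equal(hourly_average(x)$values, x$values)
  d <- daily_average(x)
  expect_equal(daily_average(d)$values, d$values)
})

test_that("only isolated single-sample gaps are interpolated", {
  x <- timeseries(c(1, NA, 3), "2007-01-01", 60)
  expect_equal(fill_small_gaps(x)$values, c(1, 2, 3))
  y <- timeseries(c(1, NA, NA, 4), "2007-01-01", 60)
  expect_identical(fill_small_gaps(y)$values, y$values)
  z <- timeseries(rep(NA_real_, 5), "2007-01-01", 60)
  expect_identical(fill_small_gaps(z)$values, z$values)
  # leading/trailing missing samples untouched; data values never altered
  w <- timeseries(c(NA, 2, NA, 4, NA), "2007-01-01", 60)
  fw <- fill_small_gaps(w)
  expect_equal(fw$values, c(NA, 2, 3, 4, NA))
})

test_that("rate transform linearises exponential growth", {
  x <- timeseries(exp(0.07 * (0:30)), "2007-01-01", 60, "chlorophyll")
  r <- log_smooth_diff(x)
  expect_length(r, 30L)
  expect_true(r$transformed)
  inner <- r$values[!is.na(r$values)]
  expect_equal(inner, rep(0.07, length(inner)))
  # constant series has zero rates
  c0 <- log_smooth_diff(timeseries(rep(5, 10), "2007-01-01", 60))
  expect_true(all(c0$values[!is.na(c0$values)] == 0))
})

test_that("rates use the smoothed log difference, not the raw difference", {
  x <- timeseries(c(1, exp(1), exp(2), exp(9)), "2007-01-01", 60)
  r <- log_smooth_diff(x)
  # smoothed logs: (NA, 1, 4, NA); last valid rate = 4 - 1 = 3, not 9 - 2
  expect_equal(r$values, c(NA, 3, NA))
})

test_that("rate transform is scale invariant and rejects non-positive data", {
  v <- exp(rnorm(50))
  a <- log_smooth_diff(timeseries(v, "2007-01-01", 60))
  b <- log_smooth_diff(timeseries(7.3 * v, "2007-01-01", 60))
  expect_equal(a$values, b$values)
  bad <- timeseries(c(1, 2, -1, 4), "2007-01-01", 60)
  expect_error(log_smooth_diff(bad), "index: 3")
})

test_that("segmentation keeps maximal runs above the strict threshold", {
  v <- c(rep(1, 50), NA, rep(1, 120), NA, rep(1, 70), NA, rep(1, 130))
  x <- timeseries(v, "2007-01-01", 60)
  segs <- find_segments(x, 101)
  expect_length(segs, 2L)
  expect_equal(vapply(segs, function(s) s$length, 0L), c(120L, 130L))
  # segments are disjoint, ordered, and do not exceed the non-missing count
  starts <- vapply(segs, function(s) s$start_index, 0L)
  expect_true(all(diff(starts) > 0))
  expect_lte(sum(vapply(segs, function(s) s$length, 0L)),
             sum(!is.na(v)))
  # extraction yields gap-free series
  s1 <- extract_segment(x, segs[[1]])
  expect_false(anyNA(s1$values))
  expect_length(s1, 120L)
})

test_that("exactly 100 consecutive hourly samples are rejected", {
  v <- c(rep(1, 100), NA, rep(1, 100))
  expect_length(find_segments(timeseries(v, "2007-01-01", 60), 101), 0L)
  expect_length(find_segments(timeseries(rep(1, 200), "2007-01-01", 60),
                              101), 1L)
})

test_that("Kd follows Beer-Lambert attenuation between 1 m and 2 m", {
  mk <- function(v) timeseries(v, "2007-01-01", 60, "par")
  expect_equal(kd_from_par(mk(100), mk(100))$values, 0)
  expect_equal(kd_from_par(mk(100), mk(100 / exp(1)))$values, 1)
  expect_equal(kd_from_par(mk(50), mk(10))$values, log(5))
  # night samples (zero irradiance) are missing, not errors
  expect_true(is.na(kd_from_par(mk(0), mk(0))$values))
})

test_that("chlorophyll-to-SPM conversion multiplies the two ratios", {
  expect_equal(chl_spm_contribution(1), 100)
  expect_equal(chl_spm_contribution(0), 0)
  expect_equal(chl_spm_contribution(2, 1, 1), 2)
  expect_error(chl_spm_contribution(-1), "non-negative")
})
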