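test_that("FFT transform matches brute-force time-domain convolution", {
  # independent oracle: explicit circular convolution with the sampled,
  # scaled, conjugated mother wavelet. Compared for scales >= 4*dt, where
  # the Morlet is band-limited well inside Nyquist so the sampled and
  # spectral daughters describe the same object.
  set.seed(42)
  n <- 256
  x <- ar1_sim(n, 0.6)
  params <- wavelet_params(pad = FALSE, s0 = 4, n_scales = 40)
  spec <- morlet_cwt(timeseries(x, "2007-01-01", 1), params)
  xd <- x - mean(x)
  direct <- matrix(0 + 0i, length(spec$scales), n)
  for (j in seq_along(spec$scales)) {
    s <- spec$scales[j]
    for (tt in seq_len(n)) {
      eta <- ((seq_len(n) - tt + n / 2) %% n - n / 2) / s
      psi <- pi^-0.25 * exp(1i * 6 * eta) * exp(-eta^2 / 2)
      direct[j, tt] <- sum(xd * Conj(psi)) * sqrt(1 / s)
    }
  }
  relerr <- max(abs(spec$wave - direct)) / max(abs(direct))
  expect_lt(relerr, 1e-6)
})

test_that("a pure sinusoid peaks at its own period, scaling as amplitude^2", {
  x <- sinusoid_ts(745.236, 1024, step = 60)
  spec <- morlet_cwt(x)
  gs <- global_spectrum(spec)
  expect_equal(as.numeric(peak_period(gs)), 745.236, tolerance = 0.03)
  # local power maximum sits at that scale band outside the COI
  j <- which.min(abs(spec$periods - 745.236))
  outside <- spec$coi > 745.236
  interior <- which(outside)
  argmax <- apply(spec$power[, interior, drop = FALSE], 2L, which.max)
  expect_true(mean(abs(spec$periods[argmax] - 745.236) / 745.236 < 0.1)
              > 0.95)
  # linearity: doubling the amplitude quadruples the power
  x2 <- x
  x2$values <- 2 * x$values
  spec2 <- morlet_cwt(x2)
  expect_equal(spec2$power, 4 * spec$power, tolerance = 1e-10)
})

test_that("transform refuses gappy or tiny segments", {
  x <- timeseries(c(1, NA, 3, 4, 5), "2007-01-01", 60)
  expect_error(morlet_cwt(x), "missing")
  expect_error(morlet_cwt(timeseries(1:3, "2007-01-01", 60)), "short")
})

test_that("the COI grows linearly and symmetrically from the edges", {
  spec <- morlet_cwt(timeseries(rnorm(200), "2007-01-01", 60))
  coi <- spec$coi
  n <- length(coi)
  half <- coi[1:(n / 2)]
  expect_true(all(diff(half) > 0))
  expect_equal(coi, rev(coi))
  expect_equal(diff(half)[10], diff(half)[80])   # linear slope
})

test_that("total wavelet power reconstructs the series variance", {
  y <- cos(2 * pi * (0:511) / 32) + 0.5 * cos(2 * pi * (0:511) / 80)
  spec <- morlet_cwt(timeseries(y, "2007-01-01", 1),
                     wavelet_params(pad = FALSE))
  ratio <- tidewave:::reconstructed_variance(spec) / stats::var(y)
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("AR(1) fitting recovers known coefficients", {
  set.seed(11)
  white <- rnorm(1e4)
  expect_lt(estimate_ar1(white)$alpha, 3 / sqrt(1e4))
  red <- ar1_sim(1e4, 0.72)
  ahat <- estimate_ar1(red)$alpha
  expect_gt(ahat, 0.69)
  expect_lt(ahat, 0.75)
  expect_error(estimate_ar1(rep(1, 100)), "constant")
  # white-noise null has a flat unit background spectrum
  p <- tidewave:::rednoise_background(0, c(120, 240, 960), 60)
  expect_equal(p, rep(1, 3))
})

test_that("white-noise significance marks ~5% of cells outside the COI", {
  set.seed(7)
  tot <- 0
  sig <- 0
  for (r in 1:200) {
    spec <- rednoise_significance(
      morlet_cwt(timeseries(rnorm(256), "2007-01-01", 60)))
    outside <- outer(spec$periods, spec$coi, `<=`)
    tot <- tot + sum(outside)
    sig <- sig + sum(spec$signif_mask[outside])
  }
  expect_gt(100 * sig / tot, 3)
  expect_lt(100 * sig / tot, 7)
})

test_that("significance saturates correctly at the extremes", {
  x <- sinusoid_ts(240, 512, step = 60)
  x$values <- x$values + rnorm(512, sd = 0.05)
  spec <- morlet_cwt(x)
  # near level 1 the threshold is effectively infinite
  hard <- rednoise_significance(spec, level = 1 - 1e-12)
  expect_lt(mean(hard$signif_mask), 0.001)
  # a strong sinusoid is flagged along its own scale band outside the COI
  soft <- rednoise_significance(spec, level = 0.95)
  j <- which.min(abs(soft$periods - 240))
  outside <- soft$coi > 240
  expect_gt(mean(soft$signif_mask[j, outside]), 0.95)
  # significance never fires inside the COI
  inside <- outer(soft$periods, soft$coi, `>`)
  expect_false(any(soft$signif_mask[inside]))
})

test_that("global spectra aggregate segments by time-point weighting", {
  x <- sinusoid_ts(240, 400, step = 60)
  spec <- morlet_cwt(x)
  g1 <- global_spectrum(spec)
  expect_equal(g1$power, rowMeans(spec$power))
  # two identical segments leave the global spectrum unchanged
  g2 <- global_spectrum(list(spec, spec))
  expect_equal(g2$power, g1$power)
  expect_equal(g2$n_timepoints, 2L * g1$n_timepoints)
  # explicit concatenated-averaging oracle for unequal segments
  a <- morlet_cwt(sinusoid_ts(240, 100, step = 60),
                  scales = spec$scales)
  b <- morlet_cwt(sinusoid_ts(480, 300, step = 60),
                  scales = spec$scales)
  g3 <- global_spectrum(list(a, b))
  oracle <- (rowSums(a$power) + rowSums(b$power)) / 400
  expect_equal(g3$power, oracle)
  # mismatched scale grids are refused
  other <- morlet_cwt(sinusoid_ts(240, 128, step = 60))
  expect_error(global_spectrum(list(spec, other)), "scale grid")
})

test_that("peak refinement is exact on a symmetric peak and flags edges", {
  x <- sinusoid_ts(240, 400, step = 60)
  gs <- global_spectrum(morlet_cwt(x))
  # symmetric triple around the maximum bin: vertex = the bin itself
  i <- which.max(gs$power)
  gs_sym <- gs
  gs_sym$power[i - 1] <- gs_sym$power[i + 1]
  expect_equal(as.numeric(peak_period(gs_sym)), gs$periods[i])
  # monotone spectrum inside a band returns the boundary bin, flagged
  band <- c(gs$periods[i] * 2, max(gs$periods))
  pk <- peak_period(gs, band)
  expect_true(isTRUE(attr(pk, "boundary")))
  expect_error(peak_period(gs, c(1, 2)), "band")
})

test_that("periods up to ~25% of the segment length are recoverable", {
  n <- 400
  x <- sinusoid_ts(0.22 * n * 60, n, step = 60)
  gs <- global_spectrum(morlet_cwt(x))
  expect_equal(as.numeric(peak_period(gs)), 0.22 * n * 60,
               tolerance = 0.05)
  # well beyond the limit the peak bin lies fully inside the COI
  y <- sinusoid_ts(0.8 * n * 60, n, step = 60)
  specy <- morlet_cwt(y, wavelet_params(n_scales = 220))
  gy <- global_spectrum(specy)
  j <- which.min(abs(gy$periods - 0.8 * n * 60))
  expect_false(any(specy$coi >= gy$periods[j]))
})
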