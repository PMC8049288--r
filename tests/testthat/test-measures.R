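mkRate <- function(t, r, dt = t[2] - t[1], sigma = 2, n = NA_integer_) {
  structure(list(t = t, r = r, kernelSigma = sigma, dt = dt, nNeurons = n),
            class = "rate_series")
}

test_that("the MUA kernel is unit-peak and additive", {
  ras <- spikeRaster(500, 1L, 1L, duration = 1000, dt = 0.01, nNeurons = 10)
  rate <- firingRate(ras, 1, kernelSigma = 2, dt = 0.5)
  expect_equal(max(rate$r), 1, tolerance = 1e-6)
  expect_equal(rate$t[which.max(rate$r)], 500)
  # symmetric bump
  i0 <- which.max(rate$r)
  expect_equal(rate$r[i0 - 4], rate$r[i0 + 4], tolerance = 1e-9)
  # two coincident spikes give peak 2
  ras2 <- spikeRaster(c(500, 500), c(1L, 2L), c(1L, 1L),
                      duration = 1000, dt = 0.01, nNeurons = 10)
  expect_equal(max(firingRate(ras2, 1, 2, 0.5)$r), 2, tolerance = 1e-6)
  # k spikes bound the rate by k
  set.seed(1)
  tt <- runif(37, 100, 900)
  rask <- spikeRaster(tt, sample(1:10, 37, TRUE), rep(1L, 37),
                      duration = 1000, dt = 0.01, nNeurons = 10)
  expect_lte(max(firingRate(rask, 1, 5, 0.5)$r), 37 + 1e-9)
  # empty raster gives an all-zero series, not an error
  rase <- spikeRaster(numeric(0), integer(0), integer(0),
                      duration = 100, dt = 0.01, nNeurons = 10)
  expect_true(all(firingRate(rase, 1, 2, 0.5)$r == 0))
})

test_that("peak detection recovers the oscillation period", {
  # deterministic periodic raster: period exactly 14 ms
  ras <- periodicRaster(N = 50, period = 14, duration = 1000, seed = 1)
  pk <- detectPeaks(firingRate(ras, 1, 2, 0.1))
  expect_equal(pk$period, 14, tolerance = 1e-6)
  # a 70 Hz sinusoidal rate gives T = 1000/70
  t <- seq(0, 1000, by = 0.1)
  pk2 <- detectPeaks(mkRate(t, 1 + 0.5 * sin(2 * pi * 70 * t / 1000)))
  expect_equal(pk2$period, 1000 / 70, tolerance = 1e-3)
  # constant rate: no oscillation to detect
  expect_error(detectPeaks(mkRate(t, rep(2, length(t)))),
               "insufficient oscillation")
})

test_that("coherency is the normalised mean peak height", {
  full <- periodicRaster(N = 80, period = 14, participation = 1,
                         duration = 600, seed = 1)
  expect_equal(coherency(firingRate(full, 1, 2, 0.1), nNeurons = 80), 1,
               tolerance = 1e-6)
  half <- periodicRaster(N = 80, period = 14, participation = 0.5,
                         duration = 600, seed = 2)
  expect_equal(coherency(firingRate(half, 1, 2, 0.1), nNeurons = 80), 0.5,
               tolerance = 3 * sqrt(0.25 / 80) / sqrt(20))
  # jitter degrades coherency below 1
  jit <- periodicRaster(N = 80, period = 14, jitterSd = 2,
                        duration = 600, seed = 3)
  expect_lt(coherency(firingRate(jit, 1, 2, 0.1), nNeurons = 80), 0.8)
  # fewer than 20 peaks is insufficient data
  short <- periodicRaster(N = 80, period = 14, duration = 150, seed = 4)
  expect_error(coherency(firingRate(short, 1, 2, 0.1), nNeurons = 80),
               "insufficient")
})

test_that("zero-lag cross-covariance uses the unbiased formula", {
  expect_equal(zeroLagCov(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(zeroLagCov(c(1, 2, 3), c(5, 5, 5)), 0)
  set.seed(2)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(zeroLagCov(x, y), zeroLagCov(y, x))
  expect_equal(zeroLagCov(x, y), cov(x, y))
  expect_error(zeroLagCov(x, y[1:50]), "equal length")
})

test_that("delayed MI is exact on a balanced binary series and non-negative", {
  x <- rep(c(0, 1), 500)
  cv <- delayedMI(x, x, dt = 1, maxLag = 3, lagStep = 1, nBins = 2)
  expect_equal(cv$dmi[cv$lag_ms == 0], 1)     # H(x) = 1 bit, exactly
  expect_true(all(cv$dmi >= -1e-12))
  # identical series: dMI(0) equals the marginal entropy for any input
  set.seed(3)
  z <- rnorm(2000)
  cz <- delayedMI(z, z, dt = 1, maxLag = 0, nBins = 8)
  bz <- table(oscflow:::binIndex(z, 8)) / 2000
  expect_equal(cz$dmi, -sum(bz * log2(bz)))
  # time reversal leaves dMI(0) unchanged
  set.seed(4)
  a <- rnorm(3000); b <- a + rnorm(3000)
  d1 <- delayedMI(a, b, dt = 1, maxLag = 0, nBins = 8)$dmi
  d2 <- delayedMI(rev(a), rev(b), dt = 1, maxLag = 0, nBins = 8)$dmi
  expect_identical(d1, d2)
  expect_error(delayedMI(a, b, dt = 1, nBins = 1), "nBins")
  expect_error(delayedMI(a[1:50], b[1:50], dt = 1, maxLag = 30), "too short")
})

test_that("MI grows with the coupling between the series", {
  m <- vapply(c(0, 0.5, 0.9), function(r) {
    gp <- gaussianPair(2e4, r, seed = 1)
    delayedMI(gp$x, gp$y, dt = 1, maxLag = 0, nBins = 16)$dmi
  }, numeric(1))
  expect_true(all(diff(m) > 0))
  expect_lt(m[1], 0.05)
})

test_that("net information integrates the lag asymmetry with the right sign", {
  # even curve integrates to zero
  even <- structure(data.frame(lag_ms = -5:5, dmi = abs(-5:5)),
                    class = c("dmi_curve", "data.frame"))
  expect_equal(netInformation(even), 0)
  # curve supported on positive lags equals its positive-lag integral
  pos <- structure(data.frame(lag_ms = -5:5,
                              dmi = c(rep(0, 5), 0, 1, 2, 2, 1, 0)),
                   class = c("dmi_curve", "data.frame"))
  expect_equal(netInformation(pos), pracma::trapz(0:5, c(0, 1, 2, 2, 1, 0)))
  expect_error(netInformation(structure(data.frame(lag_ms = 0:5, dmi = 0:5),
                                        class = c("dmi_curve", "data.frame"))),
               "symmetric")
})

test_that("a lagged copy is detected at the configured lag and direction", {
  set.seed(5)
  x <- as.numeric(stats::filter(rnorm(4000), rep(1 / 5, 5), sides = 2))
  x[is.na(x)] <- 0
  y <- laggedCopy(x, lagSteps = 10, noiseSd = 0)
  fwd <- delayedMI(x, y, dt = 1, maxLag = 20, lagStep = 1, nBins = 8)
  expect_equal(fwd$lag_ms[which.max(fwd$dmi)], 10)
  expect_gt(netInformation(fwd), 0)
  bwd <- delayedMI(y, x, dt = 1, maxLag = 20, lagStep = 1, nBins = 8)
  expect_equal(bwd$lag_ms[which.max(bwd$dmi)], -10)
  expect_lt(netInformation(bwd), 0)
  # exact estimator identity: dMI_xy(d) = dMI_yx(-d)
  expect_equal(fwd$dmi, rev(bwd$dmi))
})

test_that("locking statistics classify periodic fixtures correctly", {
  # same period, constant 3 ms offset: locked, population 1 lagging
  ras <- twoPopPeriodic(period1 = 14, period2 = 14, offset = -3,
                        duration = 1200)
  ls <- lockingStats(ras, from = 100)
  expect_true(ls$isLocked)
  expect_equal(ls$freqRatio, 1, tolerance = 1e-6)
  expect_equal(ls$phaseDiff, -2 * pi * 3 / 14, tolerance = 0.05)
  # detuned periods: frequency ratio off one, not locked
  ras2 <- twoPopPeriodic(period1 = 14, period2 = 15.5, duration = 1200)
  ls2 <- lockingStats(ras2, from = 100)
  expect_false(ls2$isLocked)
  expect_gt(abs(ls2$freqRatio - 1), 0.01)
  # the phase difference of an unlocked pair is never reported
  expect_true(is.na(ls2$phaseDiff))
})
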