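test_that("coupling combinations reduce to their trigonometric identities", {
  phi <- seq(-pi, pi, length.out = 41)
  for (d in c(0, 0.7, 2.1)) {
    expect_equal(couplingGamma(phi, d), -2 * sin(phi) * cos(d),
                 tolerance = 1e-12)
    expect_equal(couplingLambda(phi, d), -2 * cos(phi) * sin(d),
                 tolerance = 1e-12)
  }
  expect_equal(couplingGamma(0, 1.3), 0)
  expect_equal(couplingLambda(0, 0), 0)
})

test_that("the locked phase matches the closed form and keeps only stable roots", {
  for (D in c(-3, -1, 0, 1.5, 3)) for (d in c(0, 0.4, 1.0)) {
    lp <- lockedPhase(D, 4, d)
    expect_true(lp$locked)
    expect_equal(lp$phi, asin(D / (8 * cos(d))), tolerance = 1e-9)
    # stability: dGamma/dphi <= 0 at the returned root
    eps <- 1e-6
    slope <- (couplingGamma(lp$phi + eps, d) - couplingGamma(lp$phi - eps, d)) / (2 * eps)
    expect_lte(slope, 0)
    # antisymmetry in the detuning
    expect_equal(lockedPhase(-D, 4, d)$phi, -lp$phi, tolerance = 1e-9)
  }
  # beyond the locking boundary |Delta| = 2K|cos delta| there is no solution
  expect_false(lockedPhase(9, 4, 0)$locked)
  expect_false(lockedPhase(3, 4, 1.2)$locked)   # 2K cos(1.2) = 2.9 < 3
  expect_true(lockedPhase(2.8, 4, 1.2)$locked)
})

test_that("the predicted receiver response factorises as Q(beta) Q'(phi*-delta)", {
  expect_equal(nprcTheory(0, 1, 4, 0.3)$q21, 0)
  r <- nprcTheory(pi / 2, 0, 4, 0)
  expect_equal(r$q21, 1)
  expect_equal(r$transmission, 1)
  r2 <- nprcTheory(pi / 4, 2, 4, 0.5)
  phi <- asin(2 / (8 * cos(0.5)))
  expect_equal(r2$q21, sin(pi / 4) * cos(phi - 0.5), tolerance = 1e-9)
  expect_true(is.na(nprcTheory(1, 9, 4, 0)$q21))
})

test_that("the response function obeys its exact structure", {
  expect_equal(responseFunction(0, 4, 0.7), 1)
  expect_equal(imbalance(0, 4, 0.7), 0)
  # independent evaluation at Delta = 2, K = 4, delta = pi/4:
  # S = 1 + 2 / sqrt(4*16*0.5 - 4) = 1 + 2/sqrt(28)
  expect_equal(responseFunction(2, 4, pi / 4), 1 + 2 / sqrt(28),
               tolerance = 1e-12)
  expect_equal(imbalance(2, 4, pi / 4), 4 / sqrt(28), tolerance = 1e-12)
  # machine-exact symmetries
  D <- seq(-3, 3, by = 0.5)
  expect_identical(responseFunction(D, 4, 0.6) + responseFunction(-D, 4, 0.6),
                   rep(2, length(D)))
  expect_identical(imbalance(D, 4, 0.6), -imbalance(-D, 4, 0.6))
  # outside locking and at the singular delay the value is NA
  expect_true(is.na(responseFunction(9, 4, 0)))
  expect_true(is.na(responseFunction(1, 4, pi / 2)))
})

test_that("the pair simulator respects the invariant manifold and the locked state", {
  # identical oscillators, no lag, equal initial phases: phases never split
  r <- simulatePair(55, 55, 4, 0, duration = 2, dt = 1e-4)
  expect_identical(r$theta1, r$theta2)
  # locked parameters: the phase difference converges to the theory value
  r2 <- simulatePair(56, 54, 4, 0.5, duration = 6, dt = 1e-4)
  phiEnd <- r2$theta1[length(r2$theta1)] - r2$theta2[length(r2$theta2)]
  expect_equal(phiEnd, lockedPhase(2, 4, 0.5)$phi, tolerance = 1e-3)
  # collective-phase identity: locked Theta-dot equals Omega + K Lambda(phi*)
  n <- length(r2$t)
  thdot <- (r2$theta1[n] + r2$theta2[n] - r2$theta1[n - 2000] -
              r2$theta2[n - 2000]) / (r2$t[n] - r2$t[n - 2000]) / (2 * pi)
  expect_equal(thdot, 110 + 4 * couplingLambda(lockedPhase(2, 4, 0.5)$phi, 0.5),
               tolerance = 1e-3)
  # outside the locking zone the phase difference drifts
  r3 <- simulatePair(60, 50, 4, 1.3, duration = 4, dt = 1e-4)
  phi3 <- r3$theta1 - r3$theta2
  expect_gt(abs(phi3[length(phi3)] - phi3[1]), 2 * pi)
  expect_error(simulatePair(55, 55, 400, 0, 1, dt = 1e-3), "dt too large")
})

test_that("finite-difference collective response reproduces the closed form", {
  collRate <- function(w1, w2, K, d) {
    r <- simulatePair(w1, w2, K, d, duration = 6, dt = 1e-4)
    n <- length(r$t); m <- round(n / 2)
    (r$theta1[n] + r$theta2[n] - r$theta1[m] - r$theta2[m]) /
      (r$t[n] - r$t[m]) / (2 * pi)
  }
  for (cell in list(c(2, pi / 4), c(-1, 0.6), c(0, 0.9))) {
    D <- cell[1]; d <- cell[2]
    w1 <- 55 + D / 2; w2 <- 55 - D / 2
    fd <- (collRate(w1 + 1e-4, w2, 4, d) - collRate(w1, w2, 4, d)) / 1e-4
    expect_equal(fd, responseFunction(D, 4, d), tolerance = 0.01)
  }
})

test_that("the dichotomous signal is a two-state telegraph process", {
  expect_identical(dichotomousSignal(1, 10, amplitude = 0, dt = 1e-3),
                   numeric(1000))
  s <- dichotomousSignal(60, rate = 10, amplitude = 0.5, dt = 1e-3, seed = 1)
  expect_setequal(unique(s), c(-0.5, 0.5))
  runs <- rle(s)
  expect_gt(length(runs$lengths), 200)
  holding <- mean(runs$lengths[-c(1, length(runs$lengths))]) * 1e-3
  expect_equal(holding, 1 / 10, tolerance = 0.1)
})

test_that("transmission correlation separates coupled from uncoupled pairs", {
  sig <- dichotomousSignal(20, 5, 3, dt = 1e-4, seed = 2)
  # no coupling: the signal cannot reach the receiver
  r0 <- simulatePair(55, 55, 0.001, 0, duration = 20, dt = 1e-4, sigma = 1,
                     seed = 3, signal1 = sig)
  expect_lt(abs(transmissionCorrelation(r0$theta2, sig, 1e-4)), 0.12)
  # signal driving the receiver itself: near-maximal correlation
  r1 <- simulatePair(55, 55, 0.001, 0, duration = 20, dt = 1e-4, sigma = 1,
                     seed = 4, signal2 = sig)
  expect_gt(transmissionCorrelation(r1$theta2, sig, 1e-4), 0.6)
  expect_error(transmissionCorrelation(r1$theta2, rep(0, 2e5), 1e-4),
               "zero-variance")
})

test_that("delay and interaction phase convert consistently", {
  expect_equal(delayToPhase(14.29, 70), 2 * pi, tolerance = 1e-3)
  expect_equal(phaseToDelay(delayToPhase(3, 70), 70), 3)
})

test_that("theory maps carry the locking zone and its symmetries", {
  tm <- theoryMaps(4, seq(-6, 6, by = 2), c(0.3, 1.0, 2.0))
  inside <- abs(tm$Delta) < 2 * 4 * abs(cos(tm$delta))
  expect_equal(tm$locked, inside)
  expect_true(all(is.na(tm$phi_star[!tm$locked])))
  expect_true(all(is.finite(tm$S[tm$locked])))
  # zero-detuning row has zero imbalance
  expect_true(all(tm$dS[tm$Delta == 0 & tm$locked] == 0))
})
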