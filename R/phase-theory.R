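#' Antisymmetric and symmetric coupling combinations
#'
#' For two identical phase oscillators coupled through a response function
#' `Q` with interaction phase lag `delta`, the phase difference
#' `phi = theta1 - theta2` and phase sum evolve through
#' `Gamma(phi, delta) = Q(-phi - delta) - Q(phi - delta)` and
#' `Lambda(phi, delta) = Q(-phi - delta) + Q(phi - delta)`.
#'
#' @param phi phase difference (rad)
#' @param delta interaction phase lag (rad)
#' @param Q response function (callable), default `sin`
#' @return numeric
#' @export
couplingGamma <- function(phi, delta, Q = sin) Q(-phi - delta) - Q(phi - delta)

#' @rdname couplingGamma
#' @export
couplingLambda <- function(phi, delta, Q = sin) Q(-phi - delta) + Q(phi - delta)

#' Locked phase difference of two delay-coupled phase oscillators
#'
#' Solves `Gamma(phi*, delta) = -Delta / K` for the stable root
#' (`dGamma/dphi <= 0`).  The solver scans `phi` over (-pi, pi] on a dense
#' grid, brackets the sign changes, bisects each bracket to a residual below
#' 1e-10, keeps the stable roots, and returns the one closest to zero
#' (flagging multistability when more than one stable root exists).  For
#' `Q = sin` the closed form is `phi* = asin(Delta / (2 K cos delta))`
#' (small-delay branch).
#'
#' @param Delta detuning `omega1 - omega2` (same units as `K`)
#' @param K coupling strength (> 0)
#' @param delta interaction phase lag (rad)
#' @param Q response function, default `sin`
#' @param nScan scan grid size
#' @return list with `phi` (NA when no locked solution exists), `locked`,
#'   `multistable`
#' @export
lockedPhase <- function(Delta, K, delta, Q = sin, nScan = 2001) {
  stopifnot(K > 0)
  target <- -Delta / K
  g <- function(phi) couplingGamma(phi, delta, Q) - target
  # scan one step past pi so a root sitting on the periodic boundary is
  # bracketed too
  step <- 2 * pi / (nScan - 1)
  grid <- seq(-pi, pi + step, by = step)
  nG <- length(grid)
  vals <- g(grid)
  rng <- range(couplingGamma(grid, delta, Q))
  if (target <= rng[1] || target >= rng[2])
    return(list(phi = NA_real_, locked = FALSE, multistable = FALSE))
  roots <- numeric(0)
  sgn <- sign(vals)
  for (i in which(sgn[-1] * sgn[-nG] <= 0 & sgn[-nG] != 0)) {
    r <- uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-13)$root
    roots <- c(roots, r)
  }
  roots <- wrapPi(roots)
  roots <- roots[!duplicated(round(roots, 8))]
  if (!length(roots))
    return(list(phi = NA_real_, locked = FALSE, multistable = FALSE))
  eps <- 1e-6
  dG <- vapply(roots, function(r)
    (couplingGamma(r + eps, delta, Q) - couplingGamma(r - eps, delta, Q)) /
      (2 * eps), numeric(1))
  stable <- roots[dG <= 0]
  if (!length(stable))
    return(list(phi = NA_real_, locked = FALSE, multistable = FALSE))
  list(phi = stable[which.min(abs(stable))], locked = TRUE,
       multistable = length(stable) > 1)
}

#' Predicted non-local PRC of the receiver oscillator
#'
#' For a locked pair, a pulse hitting the sender at phase `beta` shifts the
#' sender by `Q(beta)` and the receiver in proportion to
#' `Q21(beta) = Q(beta) * Q'(phi* - delta)`; the transmission magnitude is
#' `|Q'(phi* - delta)|` alone.
#'
#' @inheritParams lockedPhase
#' @param beta sender pulse phase (rad)
#' @param dQ derivative of `Q`; defaults to `cos` when `Q` is `sin`, else a
#'   central finite difference
#' @return list with `q21` (signed), `transmission` (`|Q'(phi* - delta)|`),
#'   `phi`
#' @export
nprcTheory <- function(beta, Delta, K, delta, Q = sin, dQ = NULL) {
  lp <- lockedPhase(Delta, K, delta, Q)
  if (!lp$locked)
    return(list(q21 = NA_real_, transmission = NA_real_, phi = NA_real_))
  if (is.null(dQ)) {
    dQ <- if (identical(Q, sin)) cos else
      function(x) (Q(x + 1e-6) - Q(x - 1e-6)) / 2e-6
  }
  d <- dQ(lp$phi - delta)
  list(q21 = Q(beta) * d, transmission = abs(d), phi = lp$phi)
}

#' Slow-signal response function and transmission imbalance (sinusoidal Q)
#'
#' Sensitivity of the collective phase rate to a slow perturbation of the
#' sender's natural frequency, for `Q = sin`:
#' `S = 1 + Delta tan(delta) / sqrt(4 K^2 cos^2(delta) - Delta^2)`.
#' `S - 1 > 0` means the perturbation of that oscillator is amplified into
#' the collective (and hence receiver) dynamics.  The imbalance
#' `dS = S(Delta) - S(-Delta) = 2 Delta tan(delta) / sqrt(4 K^2 cos^2(delta)
#' - Delta^2)` quantifies the fast-vs-slow directional asymmetry.
#'
#' Outside the locking zone (`4 K^2 cos^2 delta - Delta^2 <= 0`) the value
#' is `NA`; at `delta = pi/2` exactly the expression is singular and `NA` is
#' returned as well.
#'
#' @inheritParams lockedPhase
#' @return numeric (vectorised over the inputs)
#' @export
responseFunction <- function(Delta, K, delta) {
  n <- max(length(Delta), length(K), length(delta))
  Delta <- rep_len(Delta, n); K <- rep_len(K, n); delta <- rep_len(delta, n)
  disc <- 4 * K^2 * cos(delta)^2 - Delta^2
  ok <- disc > 0 & abs(cos(delta)) >= 1e-12
  out <- rep(NA_real_, n)
  out[ok] <- 1 + Delta[ok] * tan(delta[ok]) / sqrt(disc[ok])
  out
}

#' @rdname responseFunction
#' @export
imbalance <- function(Delta, K, delta) {
  n <- max(length(Delta), length(K), length(delta))
  Delta <- rep_len(Delta, n); K <- rep_len(K, n); delta <- rep_len(delta, n)
  disc <- 4 * K^2 * cos(delta)^2 - Delta^2
  ok <- disc > 0 & abs(cos(delta)) >= 1e-12
  out <- rep(NA_real_, n)
  out[ok] <- 2 * Delta[ok] * tan(delta[ok]) / sqrt(disc[ok])
  out
}

#' Simulate two delay-coupled phase oscillators
#'
#' Euler-Maruyama integration of
#' `dtheta_i/dt = omega_i + s_i(t) + K sin(theta_j - theta_i - delta) +
#' noise`, with all frequencies (natural frequencies, coupling, signals,
#' noise amplitude) in Hz and `delta` an interaction phase lag in radians
#' (use [delayToPhase()] to convert a delay in ms).
#'
#' @param omega1,omega2 natural frequencies (Hz)
#' @param K coupling strength (Hz)
#' @param delta interaction phase lag (rad)
#' @param duration simulated time (s)
#' @param dt integration step (s); must satisfy `2*pi*K*dt < 0.1`
#' @param sigma white-noise amplitude (Hz)
#' @param seed RNG seed (used when `sigma > 0`)
#' @param signal1,signal2 optional per-step frequency perturbations (Hz)
#' @param theta0 initial phases (rad)
#' @param thin record every `thin`-th step (integration is unaffected);
#'   phase increments between recorded samples remain exact
#' @return list with `t` (s), `theta1`, `theta2` (rad, unwrapped) on the
#'   recorded grid of step `thin * dt`
#' @export
simulatePair <- function(omega1, omega2, K, delta, duration, dt = 1e-4,
                         sigma = 0, seed = NULL,
                         signal1 = NULL, signal2 = NULL, theta0 = c(0, 0),
                         thin = 1) {
  if (2 * pi * K * dt >= 0.1)
    stop("dt too large for the coupling strength (need 2*pi*K*dt < 0.1)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nSteps <- as.integer(floor(duration / dt + 0.5))
  duration <- nSteps * dt
  chk <- function(s) {
    if (is.null(s)) return(numeric(0))
    if (length(s) < nSteps) stop("signal shorter than the run", call. = FALSE)
    s[seq_len(nSteps)]
  }
  res <- kuramoto_pair_cpp(omega1, omega2, K, delta, sigma,
                           chk(signal1), chk(signal2),
                           duration, dt, theta0[1], theta0[2],
                           as.integer(thin))
  list(t = seq(0, by = dt * thin, length.out = length(res$theta1)),
       theta1 = res$theta1, theta2 = res$theta2)
}

#' Dichotomous (random telegraph) signal
#'
#' Two-state signal switching between `+amplitude` and `-amplitude` at
#' random times with exponentially distributed holding times of mean
#' `1/rate`.
#'
#' @param duration trace length (s)
#' @param rate switching rate (1/s, > 0)
#' @param amplitude state magnitude
#' @param dt grid step (s)
#' @param seed RNG seed
#' @return numeric vector of length `duration/dt` taking values
#'   `+-amplitude`
#' @export
dichotomousSignal <- function(duration, rate = 10, amplitude = 1, dt = 1e-4,
                              seed = 1) {
  stopifnot(rate > 0, duration > 0, dt > 0)
  n <- round(duration / dt)
  if (amplitude == 0) return(numeric(n))
  set.seed(seed)
  tm <- 0; state <- sample(c(-1, 1), 1)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    hold <- rexp(1, rate)
    j <- min(n, i + max(1L, round(hold / dt)) - 1L)
    out[i:j] <- state * amplitude
    state <- -state
    i <- j + 1L
  }
  out
}

#' Correlation between a transmitted signal and the receiver's phase rate
#'
#' Pearson correlation between the (Gaussian-smoothed) instantaneous rate of
#' change of the receiver's phase and the signal injected into the sender.
#'
#' Both series are first block-averaged onto a grid far below the smoothing
#' timescale (at most `smoothSigma / 20`, never coarser than needed), which
#' leaves the correlation unchanged while keeping long runs cheap.
#'
#' @param theta receiver phase trace (rad, length n+1)
#' @param signal injected signal (per-step, length n)
#' @param dt integration step (s)
#' @param smoothSigma Gaussian smoothing SD applied to `dtheta/dt` (s)
#' @param discard initial time to discard (s)
#' @return Pearson correlation coefficient
#' @export
transmissionCorrelation <- function(theta, signal, dt, smoothSigma = 0.05,
                                    discard = 1) {
  rate <- diff(theta) / dt
  n <- length(rate)
  if (length(signal) < n) stop("signal shorter than the phase trace", call. = FALSE)
  signal <- signal[seq_len(n)]
  fac <- max(1L, floor(max(0.002, smoothSigma / 20) / dt))
  if (fac > 1L) {
    m <- floor(n / fac)
    dim <- c(fac, m)
    rate <- colMeans(matrix(rate[seq_len(fac * m)], fac, m))
    signal <- colMeans(matrix(signal[seq_len(fac * m)], fac, m))
    dt <- dt * fac
    n <- m
  }
  if (smoothSigma > 0) {
    half <- ceiling(4 * smoothSigma / dt)
    k <- exp(-((-half:half) * dt)^2 / (2 * smoothSigma^2))
    k <- k / sum(k)
    rate <- as.numeric(stats::filter(rate, k, sides = 2))
  }
  i0 <- max(1L, round(discard / dt))
  keep <- i0:n
  keep <- keep[!is.na(rate[keep])]
  if (sd(signal[keep]) == 0 || sd(rate[keep]) == 0)
    stop("undefined correlation: zero-variance input", call. = FALSE)
  cor(rate[keep], signal[keep])
}

#' Convert between a transmission delay and an interaction phase lag
#'
#' In the phase reduction a delay `tau` (ms) acts as a phase lag
#' `delta = 2*pi*f_locked*tau/1000` (rad), with `f_locked` the common locked
#' frequency in Hz.  Valid when the delay is below or comparable to the
#' oscillation period.
#'
#' @param tauMs delay (ms)
#' @param fLockedHz locked frequency (Hz)
#' @return phase lag (rad)
#' @export
delayToPhase <- function(tauMs, fLockedHz) 2 * pi * fLockedHz * tauMs / 1000

#' @rdname delayToPhase
#' @param deltaRad phase lag (rad)
#' @export
phaseToDelay <- function(deltaRad, fLockedHz) 1000 * deltaRad / (2 * pi * fLockedHz)

#' Closed-form theory maps over a (detuning, delay) grid
#'
#' Evaluates, for sinusoidal `Q`, the locked phase difference, the
#' pulse-transmission magnitude `|Q'(phi* - delta)|`, the slow-signal
#' response function `S` and the imbalance `dS` on a grid of detuning and
#' interaction-phase values.  Cells outside the locking zone carry `NA`.
#'
#' @param K coupling strength
#' @param DeltaGrid detuning values
#' @param deltaGrid interaction phase lags (rad)
#' @return data frame with columns `Delta`, `delta`, `locked`, `phi_star`,
#'   `transmission`, `S`, `dS`
#' @export
theoryMaps <- function(K, DeltaGrid, deltaGrid) {
  g <- expand.grid(Delta = DeltaGrid, delta = deltaGrid)
  res <- mapply(function(D, d) {
    lp <- lockedPhase(D, K, d)
    c(locked = lp$locked,
      phi_star = if (lp$locked) lp$phi else NA_real_,
      transmission = if (lp$locked) abs(cos(lp$phi - d)) else NA_real_)
  }, g$Delta, g$delta)
  g$locked <- as.logical(res["locked", ])
  g$phi_star <- res["phi_star", ]
  g$transmission <- res["transmission", ]
  g$S <- responseFunction(g$Delta, K, g$delta)
  g$dS <- imbalance(g$Delta, K, g$delta)
  g
}
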