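# derived integer seed streams, kept below 2^31
seedStream <- function(seed, i) as.integer((as.double(seed) * 10007 + 7919 * i) %% 2147483629 + 1)

#' Build the standard detuned two-population network
#'
#' Population 2 is driven at `baseI0`; population 1 (the sender) at
#' `baseI0 + dI`, so `dI` sets the natural-frequency detuning.  Long-range
#' excitatory projections run in both directions with delay `delta` ms.
#'
#' @param dI detuning current (uA/cm^2), applied to population 1
#' @param delta inter-population delay (ms)
#' @param gForward,gBackward projection weights (uS/cm^2)
#' @param baseI0 mean drive of population 2 (uA/cm^2)
#' @param seed adjacency seed
#' @param ... further arguments passed to both [populationSpec()] calls
#' @return a [buildNetwork()] result
#' @export
makePair <- function(dI = 0, delta = 1, gForward = 3.75, gBackward = 3.75,
                     baseI0 = 11, seed = 1, ...) {
  buildNetwork(populationSpec(I0 = baseI0 + dI, ...),
               populationSpec(I0 = baseI0, ...),
               couplingSpec(gForward = gForward, gBackward = gBackward,
                            delta = delta),
               seed = seed)
}

#' Single-population operating-point characterisation
#'
#' Coherency index and collective oscillation frequency over a grid of mean
#' drive and noise amplitude, averaged over trials with independent
#' adjacency and noise seeds.
#'
#' @param I0Grid mean injected currents (uA/cm^2)
#' @param sigmaGrid noise amplitudes (uA/cm^2)
#' @param trials trials per cell
#' @param duration simulated time per trial (ms; 500 ms transient discarded)
#' @param seed base seed
#' @return data frame with `I0`, `sigma`, `C`, `f`, `C_sd`, `f_sd`, `trials`
#' @export
characterizePopulation <- function(I0Grid = 11, sigmaGrid = 0.5, trials = 3,
                                   duration = 3500, seed = 1) {
  g <- expand.grid(I0 = I0Grid, sigma = sigmaGrid)
  out <- lapply(seq_len(nrow(g)), function(i) {
    cc <- ff <- rep(NA_real_, trials)
    for (k in seq_len(trials)) {
      sk <- seedStream(seed, 100 * i + k)
      net <- buildNetwork(populationSpec(I0 = g$I0[i],
                                         noiseSigma = g$sigma[i]), seed = sk)
      ras <- simulateNetwork(net, duration, seed = sk + 1L)
      rate <- firingRate(ras, 1, kernelSigma = 2, dt = 0.1, from = 500)
      res <- tryCatch({
        pk <- detectPeaks(rate)
        c(coherency(rate, nNeurons = net$pops[[1]]$N), pk$frequency)
      }, error = function(e) c(NA_real_, NA_real_))
      cc[k] <- res[1]; ff[k] <- res[2]
    }
    data.frame(I0 = g$I0[i], sigma = g$sigma[i],
               C = mean(cc, na.rm = TRUE), f = mean(ff, na.rm = TRUE),
               C_sd = sd(cc), f_sd = sd(ff), trials = trials)
  })
  do.call(rbind, out)
}

#' Phase-locking sweep over detuning and delay
#'
#' @param dIGrid detuning currents (uA/cm^2)
#' @param deltaGrid inter-population delays (ms)
#' @param duration simulated time per cell (ms)
#' @param seed base seed
#' @param gForward,gBackward projection weights (uS/cm^2)
#' @return data frame with one row per cell: `dI`, `delta_ms`, `f1`, `f2`,
#'   `freq_ratio`, `phase_diff` (NA unless locked), `locked`, `flag`
#' @export
runLockingSweep <- function(dIGrid, deltaGrid, duration = 2500, seed = 1,
                            gForward = 3.75, gBackward = 3.75) {
  g <- expand.grid(dI = dIGrid, delta_ms = deltaGrid)
  out <- lapply(seq_len(nrow(g)), function(i) {
    sk <- seedStream(seed, i)
    net <- makePair(g$dI[i], g$delta_ms[i], gForward, gBackward, seed = sk)
    ras <- simulateNetwork(net, duration, seed = sk + 1L)
    ls <- tryCatch(lockingStats(ras), error = function(e) NULL)
    if (is.null(ls))
      return(data.frame(dI = g$dI[i], delta_ms = g$delta_ms[i],
                        f1 = NA, f2 = NA, freq_ratio = NA, phase_diff = NA,
                        locked = NA, flag = "insufficient-peaks"))
    data.frame(dI = g$dI[i], delta_ms = g$delta_ms[i], f1 = ls$f1, f2 = ls$f2,
               freq_ratio = ls$freqRatio, phase_diff = ls$phaseDiff,
               locked = ls$isLocked, flag = "ok")
  })
  do.call(rbind, out)
}

#' Slow-signal transmission sweep
#'
#' Injects a slow non-periodic current into the sender's excitatory neurons
#' for every (detuning, delay) cell and measures (i) the zero-lag
#' cross-covariance between the receiver's slow-smoothed firing rate and the
#' signal and (ii) the net delayed-mutual-information flow between the two
#' populations' rates.
#'
#' @inheritParams runLockingSweep
#' @param amplitude peak signal amplitude (uA/cm^2)
#' @param kernelSigma MUA kernel for the rate/ZLC measure (ms)
#' @return data frame with `dI`, `delta_ms`, `zlc`, `net_dmi`, `locked`,
#'   `flag`
#' @export
runSlowTransmissionSweep <- function(dIGrid, deltaGrid, duration = 2500,
                                     amplitude = 1, seed = 1,
                                     gForward = 3.75, gBackward = 3.75,
                                     kernelSigma = 100) {
  g <- expand.grid(dI = dIGrid, delta_ms = deltaGrid)
  absLevels <- sort(unique(abs(g$dI)))
  sigSeed <- seedStream(seed, 9999)    # one signal realisation per sweep
  out <- lapply(seq_len(nrow(g)), function(i) {
    # network/noise seeds depend on (delay, |dI|) only, so the +dI and -dI
    # cells of a pair share the adjacency, noise and signal realisations
    # (paired design)
    sk <- seedStream(seed, 97 * match(g$delta_ms[i], deltaGrid) +
                       match(abs(g$dI[i]), absLevels))
    cell <- transmissionCell(g$dI[i], g$delta_ms[i], duration, amplitude,
                             sk, gForward, gBackward, kernelSigma,
                             sigSeed = sigSeed)
    data.frame(dI = g$dI[i], delta_ms = g$delta_ms[i], zlc = cell$zlc,
               net_dmi = cell$net_dmi, locked = cell$locked, flag = cell$flag)
  })
  do.call(rbind, out)
}

# one slow-transmission cell: simulate, smooth, ZLC + net dMI
transmissionCell <- function(dI, delta, duration, amplitude, seed,
                             gForward, gBackward, kernelSigma = 100,
                             transient = 500, sigSeed = seed + 2L) {
  net <- makePair(dI, delta, gForward, gBackward, seed = seed)
  sigTrace <- if (amplitude > 0)
    makeSlowSignal(duration, dt = 0.01, amplitude = amplitude,
                   seed = sigSeed) else NULL
  ras <- simulateNetwork(net, duration, seed = seed + 1L, signal = sigTrace)
  r2 <- firingRate(ras, 2, kernelSigma = kernelSigma, dt = 1, from = transient)
  zlc <- if (is.null(sigTrace)) 0 else
    zeroLagCov(r2$r, sigTrace[pmin(length(sigTrace),
                                   round(r2$t / 0.01) + 1L)])
  # the directional (lag-resolved) dMI structure lives at the oscillation
  # timescale, so the dMI uses the fast MUA regardless of the ZLC kernel
  d1 <- firingRate(ras, 1, kernelSigma = 2, dt = 0.5, from = transient)
  d2 <- firingRate(ras, 2, kernelSigma = 2, dt = 0.5, from = transient)
  nd <- tryCatch(netInformation(delayedMI(d1$r, d2$r, dt = 0.5)),
                 error = function(e) NA_real_)
  lk <- tryCatch(lockingStats(ras)$isLocked, error = function(e) NA)
  list(zlc = zlc, net_dmi = nd, locked = lk,
       flag = if (is.na(nd)) "dmi-failed" else "ok")
}

#' Pulse-packet transmission sweep
#'
#' For each (detuning, delay) cell of a locked pair, estimates the sender's
#' population PRC and the receiver's non-local PRC from paired
#' control/pulse runs, and compares the simulated nPRC amplitude with the
#' phase-reduction prediction `pPRC(beta) * |pPRC'(phi* - delta)|` built
#' from the measured pPRC.
#'
#' @inheritParams runLockingSweep
#' @param nSegments phase segments per cycle
#' @param trials trials per segment
#' @param amplitude pulse amplitude (uA/cm^2)
#' @return list with `cells` (data frame: `dI`, `delta_ms`, `locked`,
#'   `max_nprc_sim`, `max_nprc_pred`, `flag`) and `curves` (per-cell list
#'   with `pprc` and `nprc` `prc_curve`s)
#' @export
runPulseTransmissionSweep <- function(dIGrid, deltaGrid, nSegments = 50,
                                      trials = 3, amplitude = 0.25, seed = 1,
                                      gForward = 3.75, gBackward = 3.75) {
  g <- expand.grid(dI = dIGrid, delta_ms = deltaGrid)
  curves <- vector("list", nrow(g))
  rows <- lapply(seq_len(nrow(g)), function(i) {
    sk <- seedStream(seed, i)
    net <- makePair(g$dI[i], g$delta_ms[i], gForward, gBackward, seed = sk)
    chk <- simulateNetwork(net, 2500, seed = sk + 1L)
    ls <- tryCatch(lockingStats(chk), error = function(e) NULL)
    if (is.null(ls) || !ls$isLocked)
      return(data.frame(dI = g$dI[i], delta_ms = g$delta_ms[i], locked = FALSE,
                        max_nprc_sim = NA, max_nprc_pred = NA,
                        flag = "unlocked"))
    both <- pairPulseCurves(net, nSegments, amplitude, trials, sk)
    fMean <- (ls$f1 + ls$f2) / 2
    pred <- nprcPrediction(both$pprc, ls$phaseDiff,
                           delayToPhase(g$delta_ms[i], fMean))
    curves[[i]] <<- list(pprc = both$pprc, nprc = both$nprc, pred = pred)
    data.frame(dI = g$dI[i], delta_ms = g$delta_ms[i], locked = TRUE,
               max_nprc_sim = max(abs(both$nprc$shift), na.rm = TRUE),
               max_nprc_pred = max(abs(pred), na.rm = TRUE), flag = "ok")
  })
  list(cells = do.call(rbind, rows), curves = curves)
}

# shared paired-run pPRC (sender) + nPRC (receiver) estimation
pairPulseCurves <- function(net, nSegments, amplitude, trials, seed,
                            settle = 700, width = 2) {
  delta <- net$coupling$delta
  sh1 <- matrix(NA_real_, trials, nSegments)
  sh2 <- matrix(NA_real_, trials, nSegments)
  for (k in seq_len(trials)) {
    sk <- seed + 10L * k
    ctrl <- simulateNetwork(net, settle + 200, seed = sk)
    pk <- tryCatch(detectPeaks(firingRate(ctrl, 1, 2, 0.1, from = 500)),
                   error = function(e) NULL)
    if (is.null(pk)) next
    ref <- which(pk$times > settle)[1]
    if (is.na(ref) || ref >= length(pk$times)) next
    tRef <- pk$times[ref]; Tloc <- pk$times[ref + 1] - tRef
    for (j in seq_len(nSegments)) {
      tPulse <- tRef + (j - 0.5) / nSegments * Tloc
      sig <- signalSpec("pulse", amplitude = amplitude, pulseWidth = width,
                        pulseTime = tPulse)
      run <- simulateNetwork(net, tPulse + delta + 80, seed = sk, signal = sig)
      sh1[k, j] <- pulseShift(ctrl, run, tPulse, pop = 1)
      sh2[k, j] <- pulseShift(ctrl, run, tPulse, pop = 2,
                              after = delta + width)
    }
  }
  list(pprc = prcCurve(sh1, nSegments, amplitude, width),
       nprc = prcCurve(sh2, nSegments, amplitude, width))
}

# phase-reduction prediction of the nPRC from a measured pPRC:
# pPRC(beta) * |pPRC'| evaluated at the spike-arrival phase phi* - delta
nprcPrediction <- function(pprc, phiStar, deltaPhase) {
  ph <- pprc$phase; val <- pprc$shift
  ok <- !is.na(val)
  if (sum(ok) < 4) return(rep(NA_real_, length(ph)))
  sp <- stats::smooth.spline(c(ph[ok] - 2 * pi, ph[ok], ph[ok] + 2 * pi),
                             rep(val[ok], 3), spar = 0.6)
  arrival <- (phiStar - deltaPhase) %% (2 * pi)
  dq <- stats::predict(sp, arrival, deriv = 1)$y
  stats::predict(sp, ph)$y * abs(dq)
}

#' Connection-asymmetry sweep
#'
#' Net information flow (delayed MI, no external signal) from the sender to
#' the receiver while the feedback-to-feedforward weight ratio and the delay
#' vary, at fixed positive detuning.
#'
#' @param ratioGrid `gBackward / gForward` values (0 = feedforward only)
#' @param deltaGrid inter-population delays (ms)
#' @param dI detuning current (uA/cm^2), default 0.4
#' @param gForward feedforward weight (uS/cm^2)
#' @inheritParams runLockingSweep
#' @return data frame with `ratio`, `delta_ms`, `net_dmi`, `flag`
#' @export
runAsymmetrySweep <- function(ratioGrid, deltaGrid, dI = 0.4, gForward = 3.75,
                              duration = 2500, seed = 1) {
  g <- expand.grid(ratio = ratioGrid, delta_ms = deltaGrid)
  out <- lapply(seq_len(nrow(g)), function(i) {
    sk <- seedStream(seed, i)
    cell <- transmissionCell(dI, g$delta_ms[i], duration, amplitude = 0,
                             seed = sk, gForward = gForward,
                             gBackward = g$ratio[i] * gForward)
    data.frame(ratio = g$ratio[i], delta_ms = g$delta_ms[i],
               net_dmi = cell$net_dmi, flag = cell$flag)
  })
  do.call(rbind, out)
}

#' Theory maps plus delay-coupled Kuramoto experiments
#'
#' For every (detuning, interaction-phase) cell: the closed-form locked
#' phase, pulse-transmission magnitude, response function `S` and imbalance
#' `dS`; plus, from noisy Kuramoto-pair simulations with a dichotomous
#' signal injected into either oscillator, the signal-to-receiver
#' transmission correlations in both directions and their difference (the
#' simulated transmission imbalance).
#'
#' The discrimination between the two directions rests on the
#' signal-to-noise ratio of the receiver's phase rate (a Pearson correlation
#' is insensitive to the response *gain* in the noiseless limit), so the
#' defaults pair a slow telegraph signal (holding time well above the
#' locking relaxation time) with smoothing matched to it and runs long
#' enough for the correlation difference to resolve the analytic imbalance.
#'
#' @param K coupling strength (Hz)
#' @param DeltaGrid detuning values (Hz)
#' @param deltaGrid interaction phase lags (rad)
#' @param omega base natural frequency (Hz); the pair runs at
#'   `omega +- Delta/2`
#' @param sigma phase-noise amplitude (Hz)
#' @param duration simulated time per run (s)
#' @param dt integration step (s)
#' @param rate dichotomous switching rate (1/s)
#' @param amplitude dichotomous signal amplitude (Hz)
#' @param smoothSigma smoothing of the receiver phase rate (s), passed to
#'   [transmissionCorrelation()]
#' @param seed base seed
#' @return data frame: theory columns as [theoryMaps()] plus `corr12`,
#'   `corr21`, `imbalance_sim`
#' @export
runTheoryExperiments <- function(K = 4, DeltaGrid = seq(-4, 4, by = 1),
                                 deltaGrid = (2 * (0:11) + 1) * pi / 12,
                                 omega = 55, sigma = 1, duration = 600,
                                 dt = 1e-4, rate = 2, amplitude = 1,
                                 smoothSigma = 0.25, seed = 1) {
  tm <- theoryMaps(K, DeltaGrid, deltaGrid)
  thin <- max(1L, as.integer(floor(0.002 / dt)))
  res <- lapply(seq_len(nrow(tm)), function(i) {
    sk <- seedStream(seed, i)
    D <- tm$Delta[i]; d <- tm$delta[i]
    w1 <- omega + D / 2; w2 <- omega - D / 2
    sig <- dichotomousSignal(duration, rate, amplitude, dt, seed = sk)
    nUse <- (length(sig) %/% thin) * thin
    sigDec <- colMeans(matrix(sig[seq_len(nUse)], thin))
    run12 <- simulatePair(w1, w2, K, d, duration, dt, sigma, seed = sk + 1L,
                          signal1 = sig, thin = thin)
    c12 <- transmissionCorrelation(run12$theta2, sigDec, dt * thin,
                                   smoothSigma = smoothSigma)
    run21 <- simulatePair(w1, w2, K, d, duration, dt, sigma, seed = sk + 2L,
                          signal2 = sig, thin = thin)
    c21 <- transmissionCorrelation(run21$theta1, sigDec, dt * thin,
                                   smoothSigma = smoothSigma)
    c(corr12 = c12, corr21 = c21)
  })
  res <- do.call(rbind, res)
  tm$corr12 <- res[, "corr12"]
  tm$corr21 <- res[, "corr21"]
  tm$imbalance_sim <- tm$corr12 - tm$corr21
  tm
}
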