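#' Population phase response curve (pPRC)
#'
#' Phase shift of a population's collective oscillation as a function of the
#' phase at which a brief rectangular current pulse hits its excitatory
#' neurons.  The cycle between two successive peaks of the network activity
#' is divided into `nSegments` equal segments; for each segment and trial a
#' pulse is injected at that phase and the instantaneous period `T` of the
#' cycle containing the pulse is compared with the period `T0` of the same
#' cycle in a pulse-free control run, giving `shift = (T0 - T) * 2*pi / T0`
#' (phase advance positive).
#'
#' Each trial uses an independent noise seed; the control and pulse runs of
#' a trial share the seed (identical initial state and noise draws), so the
#' pre-pulse trajectories are identical and the measured period difference
#' is purely pulse-induced.
#'
#' @param network a single-population [buildNetwork()] result
#' @param nSegments number of phase segments per cycle (default 30)
#' @param amplitude pulse amplitude (uA/cm^2, default 1)
#' @param width pulse width (ms, default 2)
#' @param trials trials per segment (default 20; independent noise seeds)
#' @param seed base RNG seed
#' @param settle time before the reference cycle (ms, > the 500 ms transient)
#' @return an object of class `prc_curve`: data frame with `phase` (segment
#'   centres, rad in \[0, 2pi)), `shift` (rad), `se` (standard error), `n`
#' @export
estimatePPRC <- function(network, nSegments = 30, amplitude = 1, width = 2,
                         trials = 20, seed = 1, settle = 700) {
  stopifnot(inherits(network, "network_spec"), nSegments >= 1, trials >= 1)
  shifts <- matrix(NA_real_, trials, nSegments)
  for (k in seq_len(trials)) {
    sk <- seed + k - 1L
    ctrlDur <- settle + 150
    ctrl <- simulateNetwork(network, ctrlDur, seed = sk)
    pk <- detectPeaks(firingRate(ctrl, 1, kernelSigma = 2, dt = 0.1, from = 500))
    ref <- which(pk$times > settle)[1]
    if (is.na(ref) || ref >= length(pk$times)) next
    tRef <- pk$times[ref]; tNext <- pk$times[ref + 1]
    Tloc <- tNext - tRef
    for (j in seq_len(nSegments)) {
      tPulse <- tRef + (j - 0.5) / nSegments * Tloc
      sig <- signalSpec("pulse", amplitude = amplitude, pulseWidth = width,
                        pulseTime = tPulse)
      run <- simulateNetwork(network, tNext + 60, seed = sk, signal = sig)
      shifts[k, j] <- pulseShift(ctrl, run, tPulse, pop = 1)
    }
  }
  prcCurve(shifts, nSegments, amplitude, width)
}

# phase shift of population `pop` induced by a pulse at tPulse, from paired
# control/pulse runs: (T0 - T) * 2*pi / T0 on the cycle containing the pulse
pulseShift <- function(ctrl, run, tPulse, pop = 1, after = 0) {
  pc <- tryCatch(detectPeaks(firingRate(ctrl, pop, 2, 0.1, from = 500)),
                 error = function(e) NULL)
  pr <- tryCatch(detectPeaks(firingRate(run, pop, 2, 0.1, from = 500)),
                 error = function(e) NULL)
  if (is.null(pc) || is.null(pr)) return(NA_real_)
  tEvent <- tPulse + after
  kc <- findInterval(tEvent, pc$times)
  kr <- findInterval(tEvent, pr$times)
  if (kc < 1 || kc >= length(pc$times) || kr < 1 || kr >= length(pr$times))
    return(NA_real_)
  T0 <- pc$times[kc + 1] - pc$times[kc]
  Tp <- pr$times[kr + 1] - pr$times[kr]
  (T0 - Tp) * 2 * pi / T0
}

prcCurve <- function(shifts, nSegments, amplitude, width) {
  mu <- colMeans(shifts, na.rm = TRUE)
  nOk <- colSums(!is.na(shifts))
  se <- apply(shifts, 2, function(z) {
    z <- z[!is.na(z)]
    if (length(z) > 1) sd(z) / sqrt(length(z)) else NA_real_
  })
  structure(data.frame(phase = (seq_len(nSegments) - 0.5) / nSegments * 2 * pi,
                       shift = mu, se = se, n = nOk),
            amplitude = amplitude, width = width,
            class = c("prc_curve", "data.frame"))
}

#' Non-local phase response curve (nPRC)
#'
#' Phase shift of the *receiver* population's oscillation caused by a pulse
#' injected into the excitatory neurons of the *sender* population, as a
#' function of the sender phase `beta` at which the pulse is applied.  The
#' pair must be phase-locked; the shift is measured on the receiver cycle
#' that contains the (delayed) arrival of the perturbed sender activity,
#' with the same paired control/pulse seed design as [estimatePPRC()].  The
#' nPRC amplitude quantifies how well spike-timing (pulse-packet) signals
#' are transmitted.
#'
#' @param network a two-population [buildNetwork()] result (population 1 is
#'   the sender)
#' @param nSegments number of sender-phase segments (default 50)
#' @param amplitude pulse amplitude (uA/cm^2, default 0.25)
#' @param width pulse width (ms, default 2)
#' @param trials trials per segment
#' @param seed base RNG seed
#' @param settle time before the reference cycle (ms)
#' @param checkLocking verify phase locking on a control run first
#' @return a `prc_curve` (see [estimatePPRC()])
#' @export
estimateNPRC <- function(network, nSegments = 50, amplitude = 0.25, width = 2,
                         trials = 20, seed = 1, settle = 700,
                         checkLocking = TRUE) {
  stopifnot(inherits(network, "network_spec"), length(network$pops) == 2)
  delta <- if (!is.null(network$coupling)) network$coupling$delta else 0
  if (checkLocking) {
    chk <- simulateNetwork(network, 2500, seed = seed + 1000L)
    ls <- lockingStats(chk)
    if (!ls$isLocked)
      stop("unlocked pair: nPRC is only defined for phase-locked populations",
           call. = FALSE)
  }
  shifts <- matrix(NA_real_, trials, nSegments)
  for (k in seq_len(trials)) {
    sk <- seed + k - 1L
    ctrl <- simulateNetwork(network, settle + 200, seed = sk)
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
      run <- simulateNetwork(network, tPulse + delta + 80, seed = sk,
                             signal = sig,
                             signalTarget = list(pop = 1, class = "E"))
      shifts[k, j] <- pulseShift(ctrl, run, tPulse, pop = 2,
                                 after = delta + width)
    }
  }
  prcCurve(shifts, nSegments, amplitude, width)
}

#' @export
print.prc_curve <- function(x, ...) {
  cat("prc_curve:", nrow(x), "segments, pulse amplitude",
      attr(x, "amplitude"), "uA/cm^2, max |shift|",
      sprintf("%.3f rad\n", max(abs(x$shift), na.rm = TRUE)))
  invisible(x)
}
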