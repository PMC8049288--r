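#' Hodgkin-Huxley membrane parameters
#'
#' Constructor for the single-compartment Hodgkin-Huxley membrane constants.
#' Defaults are the classical squid-axon values used throughout the package:
#' maximal conductances in mS/cm^2, reversal potentials in mV, capacitance in
#' uF/cm^2.
#'
#' @param C membrane capacitance (uF/cm^2)
#' @param gK,gNa,gL maximal potassium, sodium and leak conductances (mS/cm^2)
#' @param EK,ENa,EL corresponding reversal potentials (mV)
#' @return an object of class `neuron_params`
#' @examples
#' p <- neuronParams()
#' p$gNa
#' @export
neuronParams <- function(C = 1, gK = 36, gNa = 120, gL = 0.3,
                         EK = -77, ENa = 50, EL = -54.4) {
  stopifnot(C > 0, gK > 0, gNa > 0, gL > 0)
  if (!(EK < EL && EL < ENa))
    stop("reversal potentials must satisfy EK < EL < ENa", call. = FALSE)
  structure(list(C = C, gK = gK, gNa = gNa, gL = gL,
                 EK = EK, ENa = ENa, EL = EL),
            class = "neuron_params")
}

#' Synapse parameters
#'
#' Double-exponential conductance synapse: rise time `tauR`, decay time
#' `tauD` (ms, `tauR < tauD`), reversal potential `Esyn` (mV), peak
#' conductance `g` (uS/cm^2) and axonal delay `tDelay` (ms).
#'
#' @param tauR,tauD rise and decay time constants (ms)
#' @param Esyn synaptic reversal potential (mV)
#' @param g peak synaptic conductance (uS/cm^2)
#' @param tDelay axonal conduction delay (ms)
#' @return an object of class `synapse_params`
#' @export
synapseParams <- function(tauR = 0.5, tauD = 3, Esyn = 0, g = 3.75, tDelay = 0.5) {
  if (!(tauR > 0 && tauR < tauD))
    stop("synapse times must satisfy 0 < tauR < tauD", call. = FALSE)
  if (tDelay < 0) stop("tDelay must be >= 0", call. = FALSE)
  structure(list(tauR = tauR, tauD = tauD, Esyn = Esyn, g = g, tDelay = tDelay),
            class = "synapse_params")
}

#' Hodgkin-Huxley gating rate functions
#'
#' Voltage-dependent opening/closing rates (ms^-1) of the n, m and h gates.
#' The removable singularities of `alpha_n` at v = -55 mV and `alpha_m` at
#' v = -40 mV are evaluated by their analytic limits (0.1 and 1.0 ms^-1).
#'
#' @param v membrane potential(s), mV
#' @return a matrix with one row per voltage and columns
#'   `an`, `bn`, `am`, `bm`, `ah`, `bh`
#' @examples
#' gatingRates(-55)[, "an"]  # 0.1 by the analytic limit
#' @export
gatingRates <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("v must be finite numeric", call. = FALSE)
  gating_rates_cpp(as.numeric(v))
}

#' Gating steady state and time constant at clamped voltage
#'
#' @param v membrane potential (mV)
#' @return named list with `n`, `m`, `h` steady-state values
#' @export
gatingSteadyState <- function(v) {
  r <- gatingRates(v)
  list(n = unname(r[, "an"] / (r[, "an"] + r[, "bn"])),
       m = unname(r[, "am"] / (r[, "am"] + r[, "bm"])),
       h = unname(r[, "ah"] / (r[, "ah"] + r[, "bh"])))
}

#' Time derivatives of the Hodgkin-Huxley state
#'
#' Pure function returning d(v, n, m, h)/dt for a given total injected current
#' (external plus synaptic, uA/cm^2).
#'
#' @param state named numeric vector or list with `v`, `n`, `m`, `h`
#' @param ITotal total injected current (uA/cm^2)
#' @param params a [neuronParams()] object
#' @return named numeric vector `dv`, `dn`, `dm`, `dh` (per ms)
#' @export
hhDerivatives <- function(state, ITotal = 0, params = neuronParams()) {
  v <- state[["v"]]; n <- state[["n"]]; m <- state[["m"]]; h <- state[["h"]]
  if (any(!is.finite(c(v, n, m, h, ITotal))))
    stop("state and current must be finite", call. = FALSE)
  r <- gatingRates(v)
  dv <- (ITotal -
           params$gK * n^4 * (v - params$EK) -
           params$gNa * m^3 * h * (v - params$ENa) -
           params$gL * (v - params$EL)) / params$C
  c(dv = unname(dv),
    dn = unname(r[, "an"] * (1 - n) - r[, "bn"] * n),
    dm = unname(r[, "am"] * (1 - m) - r[, "bm"] * m),
    dh = unname(r[, "ah"] * (1 - h) - r[, "bh"] * h))
}

#' Resting state of the Hodgkin-Huxley neuron
#'
#' Locates the resting fixed point (all derivatives zero) for a constant
#' injected current by root-finding on dv/dt with the gates at their
#' voltage-clamped steady state.
#'
#' @param I constant injected current (uA/cm^2)
#' @param params a [neuronParams()] object
#' @param interval search interval for the resting potential (mV)
#' @return named numeric vector `v`, `n`, `m`, `h`
#' @export
hhRestingState <- function(I = 0, params = neuronParams(), interval = c(-75, -50)) {
  f <- function(v) {
    ss <- gatingSteadyState(v)
    hhDerivatives(list(v = v, n = ss$n, m = ss$m, h = ss$h), I, params)[["dv"]]
  }
  v <- uniroot(f, interval, tol = 1e-12)$root
  ss <- gatingSteadyState(v)
  c(v = v, n = unname(ss$n), m = unname(ss$m), h = unname(ss$h))
}

#' Double-exponential synaptic kernel
#'
#' Unit-peak efficacy of a chemical synapse at time `t` after spike arrival:
#' `S(t) = (exp(-t/tauD) - exp(-t/tauR)) / A` with `A` the peak value of the
#' bracket, so that `max_t S(t) = 1` and the synaptic weight is the peak
#' conductance.  `S(t) = 0` for `t <= 0`.
#'
#' @param t time since spike arrival (ms); values < 0 give 0
#' @param tauR,tauD rise and decay times (ms), `0 < tauR < tauD`
#' @return numeric vector of efficacies in \[0, 1\]
#' @examples
#' synapticKernel(synapticKernelPeakTime(0.5, 3))  # 1 at the peak
#' @export
synapticKernel <- function(t, tauR = 0.5, tauD = 3) {
  if (!(tauR > 0 && tauR < tauD))
    stop("need 0 < tauR < tauD", call. = FALSE)
  tp <- synapticKernelPeakTime(tauR, tauD)
  A <- exp(-tp / tauD) - exp(-tp / tauR)
  s <- ifelse(t <= 0, 0, (exp(-t / tauD) - exp(-t / tauR)) / A)
  pmax(s, 0)
}

#' @rdname synapticKernel
#' @export
synapticKernelPeakTime <- function(tauR = 0.5, tauD = 3) {
  if (!(tauR > 0 && tauR < tauD))
    stop("need 0 < tauR < tauD", call. = FALSE)
  tauR * tauD / (tauD - tauR) * log(tauD / tauR)
}

#' Simulate a single Hodgkin-Huxley neuron
#'
#' Integrates one isolated neuron with constant drive and additive Gaussian
#' white noise using the stochastic Euler scheme (for purely additive noise
#' the Milstein correction term vanishes, so this is the Milstein scheme as
#' well), time step `dt` ms.
#'
#' @param IExt constant injected current (uA/cm^2)
#' @param duration simulated time (ms)
#' @param dt integration step (ms), default 0.01
#' @param noiseSigma noise amplitude (uA/cm^2); 0 gives a deterministic run
#' @param seed RNG seed (used only when `noiseSigma > 0`)
#' @param init initial state; default is the resting state at I = 0
#' @param params a [neuronParams()] object
#' @param recordV record the voltage trace?
#' @return list with `spikes` (ms), `t`, `v` (if recorded), `state` (final),
#'   and `clipCount` (number of gating-variable clips to \[0, 1\])
#' @export
simulateNeuron <- function(IExt, duration, dt = 0.01, noiseSigma = 0,
                           seed = NULL, init = NULL, params = neuronParams(),
                           recordV = TRUE) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (is.null(init)) init <- hhRestingState(0, params)
  if (!is.null(seed)) set.seed(seed)
  res <- hh_network_cpp(1L, integer(0), integer(0), numeric(0), integer(0),
                        integer(0),
                        I0 = IExt, noise_sigma = noiseSigma,
                        signal = numeric(0), signal_target = FALSE,
                        duration = duration, dt = dt,
                        v0 = init[["v"]], n0 = init[["n"]],
                        m0 = init[["m"]], h0 = init[["h"]],
                        record_idx = if (recordV) 0L else integer(0),
                        tau_r = 0.5, tau_d = 3, E_exc = 0, E_inh = -80,
                        params = unlist(params),
                        spike_threshold = 0, refractory = 2)
  out <- list(spikes = res$spike_t, state = res$state,
              clipCount = res$clip_count, dt = dt, duration = duration)
  if (recordV) {
    out$t <- seq(0, duration, by = dt)
    out$v <- res$v[, 1]
  }
  out
}

#' Mean firing frequency of a spike train
#'
#' @param spikes spike times (ms)
#' @param duration total simulated time (ms)
#' @param transient initial time to discard (ms)
#' @return frequency in Hz
#' @export
spikeFrequency <- function(spikes, duration, transient = 500) {
  sp <- spikes[spikes > transient]
  1000 * length(sp) / (duration - transient)
}
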