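#' Population specification
#'
#' Describes one population of Hodgkin-Huxley neurons: size, excitatory
#' fraction, random intra-population connectivity and class-specific synaptic
#' weights (uS/cm^2; first index = postsynaptic class), mean injected current
#' and white-noise amplitude.
#'
#' @param N neuron count
#' @param fracExc fraction of excitatory neurons
#' @param pIntra intra-population connection probability (all class pairs)
#' @param gEE,gEI,gIE,gII synaptic weights (uS/cm^2): E<-E, E<-I, I<-E, I<-I
#' @param intraDelay intra-population axonal delay (ms)
#' @param I0 mean injected current (uA/cm^2)
#' @param noiseMu,noiseSigma mean and amplitude of the Gaussian white noise
#'   current (uA/cm^2)
#' @return an object of class `population_spec`
#' @export
populationSpec <- function(N = 100, fracExc = 0.8, pIntra = 0.1,
                           gEE = 3.75, gEI = 15, gIE = 7.5, gII = 15,
                           intraDelay = 0.5, I0 = 11,
                           noiseMu = 0, noiseSigma = 0.5) {
  stopifnot(N > 0, fracExc >= 0, fracExc <= 1, pIntra >= 0, pIntra <= 1,
            intraDelay >= 0, noiseSigma >= 0)
  structure(list(N = as.integer(N), fracExc = fracExc, pIntra = pIntra,
                 gEE = gEE, gEI = gEI, gIE = gIE, gII = gII,
                 intraDelay = intraDelay, I0 = I0,
                 noiseMu = noiseMu, noiseSigma = noiseSigma),
            class = "population_spec")
}

#' Inter-population coupling specification
#'
#' Long-range projections exist only between excitatory neurons.  `delta` is
#' the inter-population axonal delay in ms.
#'
#' @param pInter connection probability over ordered E-to-E pairs
#' @param gForward weight of projections population 1 -> 2 (uS/cm^2)
#' @param gBackward weight of projections population 2 -> 1 (uS/cm^2)
#' @param delta inter-population delay (ms)
#' @return an object of class `coupling_spec`
#' @export
couplingSpec <- function(pInter = 0.05, gForward = 3.75, gBackward = 3.75,
                         delta = 1) {
  stopifnot(pInter >= 0, pInter <= 1, delta >= 0, gForward >= 0, gBackward >= 0)
  structure(list(pInter = pInter, gForward = gForward,
                 gBackward = gBackward, delta = delta),
            class = "coupling_spec")
}

#' Injected signal specification
#'
#' @param kind one of `"none"`, `"slow_random"` (low-pass-filtered Gaussian
#'   noise, non-periodic) or `"pulse"` (single rectangular pulse)
#' @param amplitude signal amplitude (uA/cm^2; peak amplitude for
#'   `slow_random`)
#' @param pulseWidth pulse width (ms), for `kind = "pulse"`
#' @param pulseTime pulse onset (ms), for `kind = "pulse"`
#' @param cutoffFreq low-pass cutoff (Hz), for `kind = "slow_random"`
#' @param seed RNG seed for the signal realisation
#' @return an object of class `signal_spec`
#' @export
signalSpec <- function(kind = c("none", "slow_random", "pulse"),
                       amplitude = 1, pulseWidth = 2, pulseTime = NULL,
                       cutoffFreq = 5, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(amplitude >= 0)
  if (kind == "pulse" && pulseWidth <= 0)
    stop("pulseWidth must be > 0 for pulse signals", call. = FALSE)
  structure(list(kind = kind, amplitude = amplitude, pulseWidth = pulseWidth,
                 pulseTime = pulseTime, cutoffFreq = cutoffFreq, seed = seed),
            class = "signal_spec")
}

popClasses <- function(pop) {
  nE <- round(pop$N * pop$fracExc)
  rep(c(TRUE, FALSE), c(nE, pop$N - nE))
}

# Bernoulli edges over ordered (pre, post) pairs, self-loops excluded.
randomEdges <- function(preIds, postIds, p, sameSet) {
  if (p <= 0 || length(preIds) == 0 || length(postIds) == 0)
    return(data.frame(pre = integer(0), post = integer(0)))
  g <- expand.grid(pre = preIds, post = postIds)
  if (sameSet) g <- g[g$pre != g$post, , drop = FALSE]
  g[runif(nrow(g)) < p, , drop = FALSE]
}

#' Build an explicit one- or two-population network
#'
#' Draws the random adjacency: intra-population edges Bernoulli(`pIntra`)
#' over all ordered pairs excluding self-loops, inter-population edges
#' Bernoulli(`pInter`) over ordered excitatory-excitatory pairs only.  Fully
#' reproducible from `seed`.  Neurons are numbered 1..N1 (population 1) then
#' N1+1..N1+N2; within a population excitatory neurons come first.
#'
#' @param pop1 a [populationSpec()]
#' @param pop2 optional second [populationSpec()]
#' @param coupling optional [couplingSpec()]; requires `pop2`
#' @param seed RNG seed for the adjacency draw
#' @return an object of class `network_spec`: list with `pops`, `coupling`,
#'   `edges` (data frame `pre`, `post`, `weight`, `delay`, `inh`), `isExc`,
#'   `popId`, `nTotal`
#' @export
buildNetwork <- function(pop1, pop2 = NULL, coupling = NULL, seed = 1) {
  stopifnot(inherits(pop1, "population_spec"))
  if (!is.null(coupling) && is.null(pop2))
    stop("coupling given without a second population", call. = FALSE)
  set.seed(seed)
  pops <- if (is.null(pop2)) list(pop1) else list(pop1, pop2)
  isExc <- unlist(lapply(pops, popClasses))
  popId <- rep(seq_along(pops), vapply(pops, `[[`, integer(1), "N"))
  offset <- c(0L, pops[[1]]$N)

  edgeList <- list()
  for (k in seq_along(pops)) {
    p <- pops[[k]]
    ids <- offset[k] + seq_len(p$N)
    e <- randomEdges(ids, ids, p$pIntra, sameSet = TRUE)
    if (nrow(e)) {
      preE <- isExc[e$pre]; postE <- isExc[e$post]
      w <- ifelse(postE & preE, p$gEE,
           ifelse(postE & !preE, p$gEI,
           ifelse(!postE & preE, p$gIE, p$gII)))
      e$weight <- w
      e$delay <- p$intraDelay
      edgeList[[length(edgeList) + 1L]] <- e
    }
  }
  if (!is.null(coupling)) {
    e1 <- which(popId == 1 & isExc)
    e2 <- which(popId == 2 & isExc)
    fwd <- randomEdges(e1, e2, coupling$pInter, sameSet = FALSE)
    if (nrow(fwd)) {
      fwd$weight <- coupling$gForward; fwd$delay <- coupling$delta
      edgeList[[length(edgeList) + 1L]] <- fwd
    }
    bwd <- randomEdges(e2, e1, coupling$pInter, sameSet = FALSE)
    if (nrow(bwd)) {
      bwd$weight <- coupling$gBackward; bwd$delay <- coupling$delta
      edgeList[[length(edgeList) + 1L]] <- bwd
    }
  }
  edges <- if (length(edgeList)) do.call(rbind, edgeList) else
    data.frame(pre = integer(0), post = integer(0),
               weight = numeric(0), delay = numeric(0))
  edges <- edges[edges$weight > 0, , drop = FALSE]
  edges$inh <- !isExc[edges$pre]
  rownames(edges) <- NULL
  structure(list(pops = pops, coupling = coupling, edges = edges,
                 isExc = isExc, popId = popId, nTotal = length(isExc),
                 seed = seed),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("network_spec:", length(x$pops), "population(s),",
      x$nTotal, "neurons,", nrow(x$edges), "edges\n")
  if (!is.null(x$coupling))
    cat("  inter-population delay:", x$coupling$delta, "ms\n")
  invisible(x)
}

#' Slow non-periodic current signal
#'
#' Zero-mean band-limited random trace: Gaussian white noise generated on a
#' 1 ms grid, low-pass filtered with a 4th-order Butterworth filter at
#' `cutoffHz` (forward-backward, zero phase), linearly interpolated onto the
#' integration grid and rescaled to the requested peak amplitude.
#'
#' @param duration trace length (ms)
#' @param dt output grid step (ms)
#' @param cutoffHz low-pass cutoff (Hz), default 5
#' @param amplitude peak absolute amplitude (uA/cm^2)
#' @param seed RNG seed
#' @return numeric vector of length `duration / dt`
#' @export
makeSlowSignal <- function(duration, dt = 0.01, cutoffHz = 5, amplitude = 1,
                           seed = 1) {
  stopifnot(duration > 0, dt > 0, cutoffHz > 0)
  if (amplitude == 0) return(numeric(stepCount(duration, dt)))
  set.seed(seed)
  coarse <- 1                                   # ms
  # pad to let the filter settle and to keep the trace non-periodic
  nC <- ceiling(duration / coarse) + 2000
  w <- rnorm(nC)
  bf <- signal::butter(4, 2 * cutoffHz * coarse / 1000, type = "low")
  y <- signal::filtfilt(bf, w)
  y <- y[1001:(1000 + ceiling(duration / coarse))]
  y <- y - mean(y)
  tC <- (seq_along(y) - 1) * coarse
  tF <- (seq_len(stepCount(duration, dt)) - 1) * dt
  out <- approx(tC, y, xout = tF, rule = 2)$y
  out * (amplitude / max(abs(out)))
}

stepCount <- function(duration, dt) as.integer(floor(duration / dt + 0.5))

# Resolve a signal argument to a per-step current vector (or numeric(0)).
resolveSignal <- function(signal, duration, dt) {
  nSteps <- stepCount(duration, dt)
  if (is.null(signal)) return(numeric(0))
  if (is.numeric(signal)) {
    if (length(signal) < nSteps)
      stop("signal vector shorter than the simulation", call. = FALSE)
    return(signal[seq_len(nSteps)])
  }
  stopifnot(inherits(signal, "signal_spec"))
  switch(signal$kind,
    none = numeric(0),
    slow_random = makeSlowSignal(duration, dt, signal$cutoffFreq,
                                 signal$amplitude, signal$seed),
    pulse = {
      if (is.null(signal$pulseTime))
        stop("pulse signal needs pulseTime", call. = FALSE)
      s <- numeric(nSteps)
      i0 <- max(1L, floor(signal$pulseTime / dt) + 1L)
      i1 <- min(nSteps, ceiling((signal$pulseTime + signal$pulseWidth) / dt))
      if (i0 <= i1) s[i0:i1] <- signal$amplitude
      s
    })
}

#' Simulate a spiking network
#'
#' Integrates the full conductance-based network (time step `dt` ms, additive
#' white noise on the voltage equation) and returns the spike raster.  All
#' neurons receive their population's `I0` plus independent noise; the
#' injected signal is added only to the targeted neurons (by default the
#' excitatory neurons of population 1, the sender).  Per-edge delays are
#' rounded to the integration grid (with a warning if rounding changes the
#' value).
#'
#' Initial voltages are drawn uniformly in (-70, -60) mV with gates at their
#' steady state, from the same seed as the noise stream, so the triple
#' (network seed, simulation seed, signal seed) fully determines the output.
#'
#' @param network a [buildNetwork()] result
#' @param duration simulated time (ms); measurement runs should allow for a
#'   500 ms transient
#' @param seed RNG seed for initial conditions and noise
#' @param signal `NULL`, a [signalSpec()], or a per-step numeric vector
#'   (uA/cm^2)
#' @param signalTarget list with `pop` (population id) and `class`
#'   (`"E"` or `"I"`); default: excitatory neurons of population 1
#' @param recordV integer vector of neuron ids whose voltage to record
#' @param dt integration step (ms)
#' @return an object of class `spike_raster` (see [spikeRaster()]); the
#'   voltage traces, final state and gating clip count are attached as
#'   attributes `v`, `finalState`, `clipCount`
#' @export
simulateNetwork <- function(network, duration, seed = 1, signal = NULL,
                            signalTarget = list(pop = 1, class = "E"),
                            recordV = integer(0), dt = 0.01) {
  stopifnot(inherits(network, "network_spec"), duration > 0, dt > 0)
  duration <- stepCount(duration, dt) * dt   # snap to the integration grid
  e <- network$edges
  delaySteps <- pmax(1L, as.integer(round(e$delay / dt)))
  if (nrow(e) && any(abs(delaySteps * dt - e$delay) > 1e-9))
    warning("edge delays rounded to the dt grid")
  target <- network$popId == signalTarget$pop &
    (if (identical(signalTarget$class, "E")) network$isExc else !network$isExc)
  I0 <- rep(vapply(network$pops, `[[`, numeric(1), "I0"),
            vapply(network$pops, `[[`, integer(1), "N"))
  mu <- rep(vapply(network$pops, `[[`, numeric(1), "noiseMu"),
            vapply(network$pops, `[[`, integer(1), "N"))
  sig <- rep(vapply(network$pops, `[[`, numeric(1), "noiseSigma"),
             vapply(network$pops, `[[`, integer(1), "N"))
  set.seed(seed)
  v0 <- runif(network$nTotal, -70, -60)
  ss <- gatingSteadyState(v0)
  sigVec <- resolveSignal(signal, duration, dt)

  res <- hh_network_cpp(network$nTotal,
                        as.integer(e$pre) - 1L, as.integer(e$post) - 1L,
                        e$weight, delaySteps, as.integer(e$inh),
                        I0 = I0 + mu, noise_sigma = sig,
                        signal = sigVec, signal_target = target,
                        duration = duration, dt = dt,
                        v0 = v0, n0 = ss$n, m0 = ss$m, h0 = ss$h,
                        record_idx = as.integer(recordV) - 1L,
                        tau_r = 0.5, tau_d = 3, E_exc = 0, E_inh = -80,
                        params = unlist(neuronParams()),
                        spike_threshold = 0, refractory = 2)
  raster <- spikeRaster(time = res$spike_t,
                        neuron = res$spike_id + 1L,
                        pop = network$popId[res$spike_id + 1L],
                        duration = duration, dt = dt,
                        nNeurons = vapply(network$pops, `[[`, integer(1), "N"))
  attr(raster, "clipCount") <- res$clip_count
  attr(raster, "finalState") <- res$state
  if (length(recordV)) attr(raster, "v") <- res$v
  raster
}

#' Spike raster container
#'
#' An ordered event list (time in ms, neuron id, population id) with the run
#' geometry attached as attributes.
#'
#' @param time spike times (ms)
#' @param neuron neuron ids (global, 1-based)
#' @param pop population ids
#' @param duration run length (ms)
#' @param dt integration step (ms)
#' @param nNeurons integer vector: neurons per population
#' @return a data frame of class `spike_raster` with columns `time_ms`,
#'   `neuron_id`, `population_id`
#' @export
spikeRaster <- function(time, neuron, pop, duration, dt, nNeurons) {
  o <- order(time, neuron)
  df <- data.frame(time_ms = time[o], neuron_id = as.integer(neuron[o]),
                   population_id = as.integer(pop[o]))
  structure(df, duration = duration, dt = dt, nNeurons = as.integer(nNeurons),
            class = c("spike_raster", "data.frame"))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat("spike_raster:", nrow(x), "spikes,",
      sum(attr(x, "nNeurons")), "neurons,",
      attr(x, "duration"), "ms\n")
  invisible(x)
}
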