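# Small networks and rasters shared across test files.  Heavier simulation
# products are cached per session so several tests can reuse one run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# a standard single population raster at the default operating point
baselineRaster <- function() {
  cached("baseline", {
    net <- buildNetwork(populationSpec(), seed = 11)
    simulateNetwork(net, 2000, seed = 12)
  })
}

# two-population raster built from two periodic fixtures with a fixed offset
twoPopPeriodic <- function(period1 = 14, period2 = 14, offset = 0,
                           duration = 1000, N = 50) {
  r1 <- periodicRaster(N, period1, duration = duration, seed = 1)
  r2 <- periodicRaster(N, period2, duration = duration, seed = 2)
  spikeRaster(c(r1$time_ms, r2$time_ms + offset),
              c(r1$neuron_id, r2$neuron_id + N),
              c(rep(1L, nrow(r1)), rep(2L, nrow(r2))),
              duration = duration, dt = 0.01, nNeurons = c(N, N))
}

# hand-built two-neuron feedforward network (one neuron per "population"):
# neuron 1 fires tonically and drives neuron 2 through a single excitatory
# synapse with the given delay
twoNeuronNet <- function(delay, weight = 20, I0 = c(10, 0)) {
  mk <- function(I) populationSpec(N = 1, fracExc = 1, pIntra = 0, I0 = I,
                                   noiseSigma = 0)
  structure(list(pops = list(mk(I0[1]), mk(I0[2])), coupling = NULL,
                 edges = data.frame(pre = 1L, post = 2L, weight = weight,
                                    delay = delay, inh = FALSE),
                 isExc = c(TRUE, TRUE), popId = c(1L, 2L), nTotal = 2L,
                 seed = 1L),
            class = "network_spec")
}
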