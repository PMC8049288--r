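test_that("network construction draws the specified random adjacency", {
  # no intra edges at p = 0
  net0 <- buildNetwork(populationSpec(pIntra = 0), seed = 1)
  expect_equal(nrow(net0$edges), 0)
  # inter-population edge count within 3 binomial SDs of 80*80*0.05 = 320
  net <- buildNetwork(populationSpec(), populationSpec(),
                      couplingSpec(pInter = 0.05, delta = 2), seed = 5)
  fwd <- sum(net$edges$pre <= 100 & net$edges$post > 100)
  bwd <- sum(net$edges$pre > 100 & net$edges$post <= 100)
  sd3 <- 3 * sqrt(6400 * 0.05 * 0.95)
  expect_lt(abs(fwd - 320), sd3)
  expect_lt(abs(bwd - 320), sd3)
  # long-range projections connect excitatory neurons only
  inter <- net$edges[net$edges$pre <= 100 & net$edges$post > 100, ]
  expect_true(all(net$isExc[inter$pre]))
  expect_true(all(net$isExc[inter$post]))
  # class-specific weights: excitatory onto inhibitory carries gIE
  intra <- net$edges[net$edges$pre <= 100 & net$edges$post <= 100, ]
  ei <- intra[net$isExc[intra$pre] & !net$isExc[intra$post], ]
  expect_true(all(ei$weight == 7.5))
  ie <- intra[!net$isExc[intra$pre] & net$isExc[intra$post], ]
  expect_true(all(ie$weight == 15))
})

test_that("adjacency is reproducible from the seed and config errors are caught", {
  a <- buildNetwork(populationSpec(), populationSpec(),
                    couplingSpec(), seed = 42)
  b <- buildNetwork(populationSpec(), populationSpec(),
                    couplingSpec(), seed = 42)
  expect_identical(a$edges, b$edges)
  expect_error(buildNetwork(populationSpec(), coupling = couplingSpec()),
               "without a second population")
})

test_that("the slow signal is zero-mean, band-limited and seed-dependent", {
  expect_identical(makeSlowSignal(500, amplitude = 0), numeric(50000))
  s <- makeSlowSignal(3000, dt = 1, cutoffHz = 5, amplitude = 1, seed = 1)
  expect_equal(max(abs(s)), 1, tolerance = 1e-12)
  expect_lt(abs(mean(s)), 0.05)
  # spectral mass above twice the cutoff below 1% of the total
  sp <- Mod(stats::fft(s))^2
  fr <- (seq_along(sp) - 1) / (length(s) * 1e-3)    # Hz (dt = 1 ms)
  half <- fr <= 500
  expect_lt(sum(sp[half & fr > 10]) / sum(sp[half & fr > 0]), 0.01)
  # distinct seeds give essentially uncorrelated traces
  s2 <- makeSlowSignal(3000, dt = 1, cutoffHz = 5, amplitude = 1, seed = 2)
  expect_lt(abs(cor(s, s2)), 0.2)
})

test_that("a quiescent network produces no spikes after the onset transient", {
  # random initial voltages may release at most a rebound spike each; with
  # no drive, no noise and no synapses the network must then stay silent
  net <- buildNetwork(populationSpec(N = 10, I0 = 0, noiseSigma = 0,
                                     pIntra = 0.2), seed = 1)
  ras <- simulateNetwork(net, 400, seed = 2)
  expect_equal(sum(ras$time_ms > 100), 0)
})

test_that("the raster is fully determined by the seed triple", {
  net <- buildNetwork(populationSpec(N = 20), seed = 3)
  a <- simulateNetwork(net, 400, seed = 9)
  b <- simulateNetwork(net, 400, seed = 9)
  expect_identical(a$time_ms, b$time_ms)
  expect_identical(a$neuron_id, b$neuron_id)
  c <- simulateNetwork(net, 400, seed = 10)
  expect_false(identical(a$time_ms, c$time_ms))
})

test_that("off-grid delays are rounded with a warning", {
  net <- buildNetwork(populationSpec(N = 10, intraDelay = 0.015), seed = 1)
  expect_warning(simulateNetwork(net, 100, seed = 1), "rounded")
})

test_that("uncoupled populations with independent noise are uncorrelated", {
  net <- buildNetwork(populationSpec(), populationSpec(),
                      couplingSpec(pInter = 0, gForward = 0, gBackward = 0,
                                   delta = 1), seed = 11)
  ras <- simulateNetwork(net, 3000, seed = 4)
  # fixed-width windows would alias the coherent ~70 Hz oscillation, so the
  # comparison uses cycle-aligned spike counts (participation per cycle),
  # whose fluctuations are purely noise-driven
  cycleCounts <- function(pop) {
    pk <- detectPeaks(firingRate(ras, pop, 2, 0.1, from = 200))
    sp <- ras$time_ms[ras$population_id == pop]
    diff(findInterval(pk$times, sort(sp)))
  }
  c1 <- cycleCounts(1); c2 <- cycleCounts(2)
  m <- min(length(c1), length(c2))
  # ~190 cycles: null sd of the correlation is ~0.07
  expect_lt(abs(cor(c1[1:m], c2[1:m])), 0.3)
})

test_that("the delay line shifts the postsynaptic response by exactly the delay", {
  # one tonically spiking neuron driving a silent one: increasing the axonal
  # delay by 2 ms shifts the follower's voltage response by exactly 2 ms
  v1 <- attr(simulateNetwork(twoNeuronNet(delay = 1), 400, seed = 1,
                             recordV = 2L), "v")[, 1]
  v3 <- attr(simulateNetwork(twoNeuronNet(delay = 3), 400, seed = 1,
                             recordV = 2L), "v")[, 1]
  shift <- round(2 / 0.01)
  n <- length(v1)
  # past the initial relaxation the follower's periodic response is the
  # delay-1 response shifted by exactly 2 ms
  i0 <- round(250 / 0.01)
  expect_equal(v3[(i0 + shift):n], v1[i0:(n - shift)], tolerance = 1e-8)
})

test_that("the injected signal reaches only the targeted class", {
  # with the signal on the excitatory neurons of population 1, population 2
  # of an uncoupled pair is unaffected (identical noise stream)
  net <- buildNetwork(populationSpec(N = 20), populationSpec(N = 20),
                      couplingSpec(pInter = 0, gForward = 0, gBackward = 0,
                                   delta = 1), seed = 6)
  sig <- rep(0.5, 40000)
  a <- simulateNetwork(net, 400, seed = 8)
  b <- simulateNetwork(net, 400, seed = 8, signal = sig,
                       signalTarget = list(pop = 1, class = "E"))
  expect_identical(a$time_ms[a$population_id == 2],
                   b$time_ms[b$population_id == 2])
  expect_false(identical(a$time_ms[a$population_id == 1],
                         b$time_ms[b$population_id == 1]))
})
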