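#' Periodic spike raster with known ground truth
#'
#' Deterministic oracle for the analysis layer: every `period` ms a
#' Bernoulli(`participation`) subset of the `N` neurons fires at the cycle
#' time plus independent Gaussian jitter.  With `participation = 1` and zero
#' jitter the coherency index is exactly 1 and the detected period is
#' exactly `period`.
#'
#' @param N neuron count
#' @param period cycle length (ms)
#' @param participation per-cycle firing probability of each neuron
#' @param jitterSd spike-time jitter SD (ms)
#' @param duration raster length (ms)
#' @param seed RNG seed
#' @return a [spikeRaster()] (population id 1)
#' @export
periodicRaster <- function(N = 100, period = 14, participation = 1,
                           jitterSd = 0, duration = 1000, seed = 1) {
  stopifnot(period > 0, participation >= 0, participation <= 1)
  set.seed(seed)
  cycles <- seq(period, duration - period / 2, by = period)
  tt <- numeric(0); id <- integer(0)
  for (tc in cycles) {
    who <- which(runif(N) < participation)
    if (!length(who)) next
    times <- rep(tc, length(who)) +
      if (jitterSd > 0) rnorm(length(who), 0, jitterSd) else 0
    keep <- times > 0 & times < duration
    tt <- c(tt, times[keep]); id <- c(id, who[keep])
  }
  spikeRaster(tt, id, rep(1L, length(tt)), duration = duration, dt = 0.01,
              nNeurons = N)
}

#' Bivariate Gaussian series with known mutual information
#'
#' Samples `n` pairs from a standard bivariate normal with correlation
#' `rho`.  The analytic mutual information `-0.5 * log2(1 - rho^2)` bits is
#' attached as ground truth.
#'
#' @param n sample count
#' @param rho correlation, `|rho| < 1`
#' @param seed RNG seed
#' @return list with `x`, `y` and `mi` (bits)
#' @export
gaussianPair <- function(n, rho, seed = 1) {
  stopifnot(abs(rho) < 1, n > 1)
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  list(x = x, y = y, mi = -0.5 * log2(1 - rho^2))
}

#' Lagged noisy copy of a series
#'
#' `y(t) = x(t - lag) + noise`; with small noise the delayed mutual
#' information from `x` to `y` peaks at `+lag`.
#'
#' @param x source series
#' @param lagSteps lag in grid steps (integer >= 0)
#' @param noiseSd additive Gaussian noise SD
#' @param seed RNG seed
#' @return numeric vector of the same length as `x` (leading values repeat
#'   the first sample)
#' @export
laggedCopy <- function(x, lagSteps, noiseSd = 0, seed = 1) {
  stopifnot(lagSteps >= 0, lagSteps == round(lagSteps))
  set.seed(seed)
  n <- length(x)
  y <- c(rep(x[1], lagSteps), x)[seq_len(n)]
  if (noiseSd > 0) y <- y + rnorm(n, 0, noiseSd)
  y
}
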