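#' Multi-unit activity (instantaneous firing rate)
#'
#' Smooths the spike raster of one population with a unit-peak Gaussian
#' kernel: `r(t) = sum_spikes exp(-(t - t_s)^2 / (2 sigma^2))`, i.e. a
#' weighted spike count in a sliding window.  With a unit-peak kernel, `k`
#' perfectly coincident spikes give a peak of exactly `k`, which is what the
#' coherency normalisation relies on.  A standard deviation of 2 ms resolves
#' the fast (gamma-cycle) modulation; 100 ms tracks slow rate modulation.
#'
#' @param raster a [spikeRaster()]
#' @param pop population id to smooth
#' @param kernelSigma Gaussian kernel standard deviation (ms)
#' @param dt output grid step (ms)
#' @param from,to time range (ms); defaults to the full run
#' @return an object of class `rate_series`: list with `t`, `r`,
#'   `kernelSigma`, `dt`, `nNeurons`
#' @export
firingRate <- function(raster, pop = 1, kernelSigma = 2, dt = 0.5,
                       from = 0, to = NULL) {
  stopifnot(kernelSigma > 0, dt > 0)
  if (is.null(to)) to <- attr(raster, "duration")
  sp <- raster$time_ms[raster$population_id == pop]
  grid <- seq(from, to, by = dt)
  cnt <- numeric(length(grid))
  if (length(sp)) {
    idx <- round((sp - from) / dt) + 1
    keep <- idx >= 1 & idx <= length(grid)
    cnt <- tabulate(idx[keep], nbins = length(grid))
  }
  half <- ceiling(4 * kernelSigma / dt)
  kern <- exp(-((-half:half) * dt)^2 / (2 * kernelSigma^2))
  r <- as.numeric(stats::filter(cnt, kern, sides = 2))
  r[is.na(r)] <- 0
  nn <- attr(raster, "nNeurons")
  structure(list(t = grid, r = r, kernelSigma = kernelSigma, dt = dt,
                 nNeurons = if (!is.null(nn)) nn[pop] else NA_integer_),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat("rate_series:", length(x$t), "samples, dt =", x$dt,
      "ms, kernel sigma =", x$kernelSigma, "ms\n")
  invisible(x)
}

#' Oscillation peaks and mean period of a rate series
#'
#' Local maxima of the population activity above a prominence floor
#' (`minHeightFrac` of the series maximum) and separated by at least
#' `minDistMs`.  The mean interval between successive peaks is the
#' oscillation period.
#'
#' @param rate a [firingRate()] result (fast kernel, sigma = 2 ms)
#' @param minHeightFrac height floor as a fraction of the maximum
#' @param minDistMs minimal peak separation (ms)
#' @return list with `times` (ms), `heights`, `period` (ms), `frequency`
#'   (Hz), `n`
#' @export
detectPeaks <- function(rate, minHeightFrac = 0.3, minDistMs = 4) {
  r <- rate$r
  if (max(r) - min(r) < sqrt(.Machine$double.eps) || length(r) < 5)
    stop("insufficient oscillation: rate series has no structure", call. = FALSE)
  pk <- pracma::findpeaks(r, minpeakheight = minHeightFrac * max(r),
                          minpeakdistance = max(1L, round(minDistMs / rate$dt)))
  if (is.null(pk) || nrow(pk) < 3)
    stop("insufficient oscillation: fewer than 3 peaks detected", call. = FALSE)
  o <- order(pk[, 2])
  times <- rate$t[pk[o, 2]]
  per <- mean(diff(times))
  list(times = times, heights = pk[o, 1], period = per,
       frequency = 1000 / per, n = length(times))
}

#' Coherency index of a population
#'
#' Mean of `nPeaks` successive peak amplitudes of the population activity
#' (sigma = 2 ms Gaussian kernel), normalised by the peak obtained when all
#' `N` neurons fire simultaneously (which is `N` under the unit-peak
#' kernel).  `C = 1` means perfect synchrony.
#'
#' @param rate a [firingRate()] result
#' @param nNeurons number of neurons in the population (defaults to the
#'   value recorded in `rate`)
#' @param nPeaks number of successive peaks to average (default 20)
#' @param ... passed to [detectPeaks()]
#' @return coherency index in \[0, 1\]
#' @export
coherency <- function(rate, nNeurons = NULL, nPeaks = 20, ...) {
  if (is.null(nNeurons)) nNeurons <- rate$nNeurons
  if (is.null(nNeurons) || is.na(nNeurons))
    stop("nNeurons must be supplied", call. = FALSE)
  pk <- detectPeaks(rate, ...)
  if (pk$n < nPeaks)
    stop("insufficient data: fewer than ", nPeaks, " peaks", call. = FALSE)
  mean(pk$heights[seq_len(nPeaks)]) / nNeurons
}

#' Unbiased, unnormalised cross-covariance at zero lag (ZLC)
#'
#' `ZLC = sum((x - mean(x)) (y - mean(y))) / (n - 1)`.  Used to quantify how
#' well the receiver population's firing rate follows the injected signal.
#'
#' @param x,y numeric vectors of equal length (n >= 2)
#' @return the zero-lag cross-covariance
#' @examples
#' zeroLagCov(c(1, 2, 3), c(1, 2, 3))  # 1
#' @export
zeroLagCov <- function(x, y) {
  if (inherits(x, "rate_series")) x <- x$r
  if (inherits(y, "rate_series")) y <- y$r
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
}

# plug-in mutual information (bits) on equal-width bins
miPlugin <- function(x, y, nBins) {
  miBinned(binIndex(x, nBins), binIndex(y, nBins), nBins)
}

miBinned <- function(bx, by, nBins) {
  n <- length(bx)
  px <- tabulate(bx, nBins) / n
  py <- tabulate(by, nBins) / n
  pxy <- tabulate(bx + nBins * (by - 1L), nBins * nBins) / n
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  ent(px) + ent(py) - ent(pxy)
}

# Equal-width bins over a robust (0.1%-99.9% percentile) range; samples
# beyond it are winsorised into the end bins.  Binning over the raw observed
# range would let a handful of extreme samples dilate the bins and inflate
# the discretisation loss of the estimator.
binIndex <- function(x, nBins) {
  rng <- unname(stats::quantile(x, c(0.001, 0.999), names = FALSE))
  if (rng[2] <= rng[1]) rng <- range(x)
  if (rng[2] == rng[1]) return(rep(1L, length(x)))
  i <- findInterval(x, seq(rng[1], rng[2], length.out = nBins + 1),
                    all.inside = TRUE)
  as.integer(pmin(pmax(i, 1L), nBins))
}

#' Delayed mutual information between two series
#'
#' Plug-in estimate of `dMI(d) = H(X(t)) + H(Y(t+d)) - H(X(t), Y(t+d))`
#' (base-2 logarithms, bits) on equal-width bins over each series' observed
#' range, computed over a symmetric grid of lags.  Positive lags quantify
#' information flowing x -> y.
#'
#' @param x,y numeric vectors on a common time grid (typically two
#'   populations' firing rates)
#' @param dt grid step of the series (ms)
#' @param maxLag maximal absolute lag (ms)
#' @param lagStep lag grid step (ms); must be a multiple of `dt`.  The
#'   default uses 0.5 ms when the series grid allows it and `dt` otherwise
#' @param nBins number of equal-width bins per series (>= 2)
#' @return an object of class `dmi_curve`: data frame with `lag_ms` and
#'   `dmi` (bits), lag grid symmetric about zero; `nBins` and `dt` attached
#'   as attributes
#' @export
delayedMI <- function(x, y, dt, maxLag = 30, lagStep = NULL, nBins = 16) {
  if (inherits(x, "rate_series")) { dt <- x$dt; x <- x$r }
  if (inherits(y, "rate_series")) y <- y$r
  if (is.null(lagStep))
    lagStep <- if (0.5 >= dt && abs(0.5 / dt - round(0.5 / dt)) < 1e-8) 0.5 else dt
  if (nBins < 2) stop("nBins must be >= 2", call. = FALSE)
  if (length(x) != length(y))
    stop("x and y must share the time grid", call. = FALSE)
  step <- lagStep / dt
  if (abs(step - round(step)) > 1e-8)
    stop("lagStep must be a multiple of dt", call. = FALSE)
  step <- as.integer(round(step))
  maxK <- as.integer(floor(maxLag / lagStep))
  lagsK <- (-maxK:maxK) * step
  n <- length(x)
  if (n - max(abs(lagsK)) < 10 * nBins)
    stop("series too short for the requested lags (need >= 10*nBins overlap)",
         call. = FALSE)
  # bin each series once over its full observed (robust) range so that all
  # lags share the same partition
  bx <- binIndex(x, nBins); by <- binIndex(y, nBins)
  dmi <- vapply(lagsK, function(k) {
    if (k >= 0) miBinned(bx[1:(n - k)], by[(1 + k):n], nBins)
    else miBinned(bx[(1 - k):n], by[1:(n + k)], nBins)
  }, numeric(1))
  structure(data.frame(lag_ms = lagsK * dt, dmi = dmi),
            nBins = nBins, dt = dt,
            class = c("dmi_curve", "data.frame"))
}

#' Net information flow from a delayed-MI curve
#'
#' Trapezoidal integral of the dMI over positive lags minus the integral
#' over negative lags (bits * ms).  Positive values indicate net information
#' flow x -> y.
#'
#' @param curve a [delayedMI()] result (symmetric lag grid)
#' @return signed scalar (bits * ms)
#' @export
netInformation <- function(curve) {
  lag <- curve$lag_ms; dmi <- curve$dmi
  if (!isTRUE(all.equal(sort(lag), sort(-lag))))
    stop("lag grid must be symmetric about 0", call. = FALSE)
  pos <- lag >= 0; neg <- lag <= 0
  pracma::trapz(lag[pos], dmi[pos]) - pracma::trapz(-rev(lag[neg]), rev(dmi[neg]))
}

circMean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))
circSD <- function(theta) {
  R <- sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)
  sqrt(-2 * log(max(R, .Machine$double.eps)))
}

#' Phase-locking statistics of two simulated populations
#'
#' Detects the oscillation peaks of both populations, forms the frequency
#' ratio `f1/f2` and the per-cycle phase offsets `2*pi*(p - q_j)/(q_{j+1} -
#' q_j)` of population-1 peaks within population-2 cycles, and classifies
#' the pair as locked when three criteria hold: `|f1/f2 - 1| < tol`,
#' circular SD of the offsets `< circTol`, and no systematic drift of the
#' offsets (absolute circular-mean difference between the two halves of the
#' run `< driftTol`; uncoupled equal-frequency populations keep a ratio near
#' 1 while their phase offset random-walks, and the drift statistic rejects
#' them).  The phase difference (`phi1 - phi2`, positive when population 1
#' leads, wrapped to (-pi, pi]) is reported only for locked pairs.
#'
#' @param raster a two-population [spikeRaster()]
#' @param from analysis start (ms), discarding the transient
#' @param tol frequency-ratio tolerance
#' @param circTol circular-SD tolerance (rad)
#' @param driftTol half-to-half circular-mean drift tolerance (rad)
#' @param kernelSigma,dt passed to [firingRate()]
#' @return an object of class `locking_result`: list with `freqRatio`,
#'   `phaseDiff` (NA when unlocked), `isLocked`, `f1`, `f2`, `circSD`,
#'   `drift`
#' @export
lockingStats <- function(raster, from = 500, tol = 0.01, circTol = 0.5,
                         driftTol = 0.25, kernelSigma = 2, dt = 0.1) {
  r1 <- firingRate(raster, 1, kernelSigma, dt, from = from)
  r2 <- firingRate(raster, 2, kernelSigma, dt, from = from)
  p1 <- detectPeaks(r1); p2 <- detectPeaks(r2)
  ratio <- p1$frequency / p2$frequency
  q <- p2$times
  # a population-1 peak at time p after a population-2 peak q_j means
  # population 1 lags by 2*pi*(p - q_j)/cycle, hence the minus sign
  offs <- vapply(p1$times, function(p) {
    j <- findInterval(p, q)
    if (j < 1 || j >= length(q)) return(NA_real_)
    -2 * pi * (p - q[j]) / (q[j + 1] - q[j])
  }, numeric(1))
  offs <- offs[!is.na(offs)]
  csd <- if (length(offs) >= 3) circSD(offs) else Inf
  drift <- if (length(offs) >= 6) {
    h <- floor(length(offs) / 2)
    abs(wrapPi(circMean(offs[(h + 1):(2 * h)]) - circMean(offs[1:h])))
  } else Inf
  locked <- abs(ratio - 1) < tol && csd < circTol && drift < driftTol
  structure(list(freqRatio = ratio,
                 phaseDiff = if (locked) wrapPi(circMean(offs)) else NA_real_,
                 isLocked = locked, f1 = p1$frequency, f2 = p2$frequency,
                 circSD = csd, drift = drift),
            class = "locking_result")
}

wrapPi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}

#' @export
print.locking_result <- function(x, ...) {
  cat(sprintf("locking_result: f1 = %.2f Hz, f2 = %.2f Hz, ratio = %.4f, %s\n",
              x$f1, x$f2, x$freqRatio,
              if (x$isLocked) sprintf("locked (phase diff %.3f rad)", x$phaseDiff)
              else "not locked"))
  invisible(x)
}
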