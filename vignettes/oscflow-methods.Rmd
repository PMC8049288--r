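---
title: "Delay and detuning as regulators of inter-population signal flow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay and detuning as regulators of inter-population signal flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

oscflow studies a specific question in the communication-through-coherence
(CTC) framework: when two neural populations each generate a collective
gamma-band oscillation, how do the axonal conduction delay of their mutual
projections and the mismatch (detuning) of their natural frequencies decide
whether a signal injected into one population reaches the other, and in
which direction information flows preferentially?  The package contains the
three layers needed to answer it: a spiking-network simulator, the
measurement layer, and a two-oscillator phase reduction that predicts the
simulation maps.

## The spiking model

Each neuron is a single-compartment Hodgkin-Huxley model with the classical
squid-axon constants (`neuronParams()`: C = 1 uF/cm^2, gK = 36, gNa = 120,
gL = 0.3 mS/cm^2, EK = -77, ENa = 50, EL = -54.4 mV).  The gating rates are
the standard voltage-dependent expressions; the removable singularities of
the n- and m-gate opening rates (at -55 and -40 mV) are evaluated by their
analytic limits whenever the voltage is within 1e-7 mV of the singular
point.  Integration is stochastic Euler at dt = 0.01 ms with additive
Gaussian white noise (sigma * sqrt(dt) per step) on the voltage equation
only; for additive noise the Milstein correction term vanishes, so the
scheme is simultaneously the Milstein scheme, and the test suite verifies
bit-level agreement with an independent R-level Euler-Maruyama loop.
Gating variables are clipped to [0, 1] after each step and clips are
counted (they occur only under extreme noise).

Synapses are conductance-based with a double-exponential kernel
(rise 0.5 ms, decay 3 ms for both AMPA-like and GABA_A-like synapses,
reversal potentials 0 and -80 mV).  The kernel is normalised to unit peak,
so the tabulated weights are peak conductances, and the synaptic current is
g S(t) (E_syn - v) — the driving-force convention under which excitatory
synapses depolarise.  Spikes are registered at upward crossings of 0 mV
with a 2 ms lockout; 0 mV is unambiguous for full-height HH spikes, whose
amplitude reaches ~+40 mV.

A population is 100 neurons, 80% excitatory, with 10% random connectivity
for every class pair and a fixed 0.5 ms intra-population delay.  Every
neuron receives a mean drive I0 plus independent white noise (sigma = 0.5
uA/cm^2).  At I0 = 11 uA/cm^2 the population synchronises into a collective
oscillation at roughly 70 Hz with coherency index about 0.8, while single
neurons fire at 70-73 Hz over the 10-12 uA/cm^2 drive range.  Two
populations are coupled by long-range excitatory-to-excitatory projections
drawn with probability 5% per ordered pair, with a single scalar delay
delta (0-14 ms) per direction.  The long-range weight is not fixed by the
study conditions elsewhere in the package, so it needed a choice: the
default is 3.75 uS/cm^2, i.e. the same strength as a local E-to-E synapse,
which gives each excitatory neuron roughly four long-range inputs against
eight local ones and produces a locking window of about +-0.5 uA/cm^2 of
detuning at small delays — wide enough to explore, narrow enough that the
detuning grid (+-0.4 uA/cm^2) spans both locked and unlocked cells.
Detuning is imposed as I0 = 11 + dI on population 1 (the sender) with
population 2 fixed at 11.

## Signals

Two signal classes probe the two neural coding regimes.

*Slow (rate-coded) signals.* A zero-mean, non-periodic current obtained by
low-pass filtering white Gaussian noise with a 4th-order Butterworth filter
at 5 Hz (forward-backward, so zero phase), rescaled to a 1 uA/cm^2 peak by
default, and injected into the sender's excitatory neurons on top of I0.
The amplitude is a configuration knob; 1 uA/cm^2 modulates the sender's
oscillation frequency by roughly +-1.5 Hz.

*Pulse packets (time-coded signals).* A single rectangular current pulse
(0.25 uA/cm^2, 2 ms for transmission experiments; 1 uA/cm^2, 2 ms for
population-PRC estimation) applied to all excitatory neurons of a
population at a controlled phase of its cycle, the cycle being divided into
50 segments for transmission tests and 30 for PRC estimation.

## Measures

*Multi-unit activity (MUA).* Spike trains smoothed with a unit-peak
Gaussian kernel — a weighted spike count, so k coincident spikes give a
peak of exactly k.  Kernel sigma = 2 ms resolves the gamma cycle; 100 ms
tracks slow rate modulation.

*Coherency.* The mean of 20 successive peaks of the fast MUA divided by
the value that would result if all N neurons fired simultaneously (which
is N, by the unit-peak kernel).  C = 1 is perfect synchrony.

*Oscillation period.* Local maxima of the fast MUA above 30% of the series
maximum and at least 4 ms apart; the period is the mean inter-peak
interval.  Fewer than three peaks raises an insufficient-oscillation error.

*ZLC.* The unbiased, unnormalised zero-lag cross-covariance between the
receiver's slow MUA and the injected signal.

*Delayed mutual information.* The plug-in histogram estimator of
I(X(t); Y(t+d)) in bits over a symmetric lag grid (default +-30 ms in
0.5 ms steps, 16 equal-width bins).  Binning uses each series' 0.1-99.9
percentile range with more extreme samples winsorised into the end bins:
binning over the raw observed range would let a handful of extreme samples
dilate the bins, and the resulting discretisation loss grows with the
sample size (measured: ~11% of the Gaussian benchmark MI at n = 1e5 versus
~6% with the robust range).  Both series are binned once over their full
range so all lags share one partition, which also makes dMI(x, x, 0)
exactly the plug-in marginal entropy.  No bias correction is applied; the
first-order bias of the independent-series estimate is
(B-1)^2 / (2 n ln 2) bits, and because that formula is also the *mean* of
the estimate under independence when all bins are occupied, individual
realisations land on either side of it.  The net information flow is the
trapezoidal integral of the dMI over positive lags minus the integral over
negative lags; positive values mean net flow from the first series to the
second.  The lag-resolved directional structure lives at the oscillation
timescale, so net-dMI computations use the fast (2 ms) MUA even in
slow-signal experiments.

*Phase locking.* The frequency ratio of the two populations' MUA peaks and
the circular statistics of per-cycle peak offsets.  A pair is locked when
|f1/f2 - 1| < 0.01, the circular SD of the offsets is below 0.5 rad, and
the offsets show no systematic drift (circular-mean difference between the
two halves of the run below 0.25 rad).  The third criterion was added
because uncoupled populations with equal mean frequency keep a ratio near 1
while their offset random-walks slowly; the 0.25 rad tolerance was
calibrated on pilot runs of uncoupled versus weakly-detuned locked pairs
(drift statistic ~0.05 rad when locked, typically 0.15-0.6 rad over 2 s
when uncoupled — short runs can still occasionally slip through).  The
phase difference phi1 - phi2 (positive when the sender leads, wrapped to
(-pi, pi]) is reported only for locked pairs.

*Population and non-local PRCs.* The pPRC is the phase advance of the
population's next activity peak as a function of the pulse phase,
shift = (T0 - T) 2 pi / T0, where T is the inter-peak interval of the cycle
containing the pulse and T0 the same interval in a control run.  Control
and pulse runs share the noise seed, so the pre-pulse trajectories are
identical and the measured difference is purely pulse-induced; this paired
design lets a handful of trials do the work of many independent ones.  The
nPRC applies the pulse to the sender and measures the receiver's peak
shift on the cycle containing the delayed arrival; it requires a locked
pair.  Only the first affected cycle is scored — later cycles mix the
direct effect with re-locking dynamics.

## The phase reduction

Two phase oscillators with natural frequencies omega_i, symmetric coupling
K and response function Q interact through a phase-lagged argument,
theta_j - theta_i - delta, where delta = 2 pi f_locked tau / 1000 converts
a conduction delay tau (ms) to an interaction phase — an approximation
valid while the delay stays below or near one period.  With
phi = theta1 - theta2 and Delta = omega1 - omega2, the reduced dynamics
run through Gamma(phi, delta) = Q(-phi - delta) - Q(phi - delta) and
Lambda(phi, delta) = Q(-phi - delta) + Q(phi - delta): locked states solve
Gamma(phi*, delta) = -Delta / K with dGamma/dphi <= 0, which for Q = sin
gives sin(phi*) = Delta / (2 K cos delta) and the locking boundary
|Delta| = 2 K |cos delta|.  The root finder scans phi over (-pi, pi] on a
2001-point grid (plus one wrap-around interval so boundary roots at +-pi
are bracketed), bisects every sign change, keeps the stable roots and
returns the one closest to zero, flagging multistability.

A pulse that hits the sender at phase beta shifts it by Q(beta) and the
receiver, to first order, by Q21 = Q(beta) Q'(phi* - delta): the factor
|Q'(phi* - delta)| is the pulse-transmission gain of the channel.  For slow
signals the response function S = dTheta-dot/d omega1 (Theta = theta1 +
theta2) measures how strongly a perturbation of the sender's frequency
drives the collective — and hence the receiver's — rate; for sinusoidal Q,
S = 1 + Delta tan(delta) / sqrt(4 K^2 cos^2 delta - Delta^2), and the
imbalance dS = S(Delta) - S(-Delta) quantifies the directional asymmetry.
For delays below a quarter period the faster oscillator transmits better;
for phases between pi/2 and pi the preference reverses.  Both formulas are
singular exactly at delta = pi/2 and undefined outside locking; the
implementation returns NA there rather than raising.

The Kuramoto-pair simulator integrates the two-oscillator system by
Euler-Maruyama (frequencies in Hz, noise in Hz, default dt = 1e-4 s) and is
used in two roles: as an independent numerical oracle for the closed forms
(finite-difference dTheta-dot/d omega reproduces S to better than 1%), and
to replay the transmission experiment with a dichotomous telegraph signal.
One point deserves emphasis because it shaped the defaults: a Pearson
correlation between the receiver's smoothed phase rate and the signal is
insensitive to the response *gain* in the noiseless limit (the response is
the signal rescaled, so the correlation saturates near 1 in both
directions).  The direction discrimination therefore rests entirely on the
signal-to-noise ratio, and the defaults are chosen by that analysis:
switching rate 2 1/s (holding time well above the ~5 ms re-locking time),
signal amplitude 1 Hz (small against omega = 55 Hz and K = 4 but visible
against the phase noise sigma = 1 Hz), rate smoothing 0.25 s, and 600 s
runs so the correlation difference resolves the analytic imbalance on all
but the smallest-|dS| cells.

## Fixtures as oracles

The measurement layer is tested against inputs with known ground truth
rather than against the simulator: periodic rasters (exact period,
coherency equal to the participation fraction), bivariate Gaussian series
(MI = -0.5 log2(1 - rho^2) bits), and lagged noisy copies (dMI peak at the
configured lag, known flow direction).  These fixtures are deliberately
unrealistic — no refractoriness, no rate fluctuations — so a passing test
certifies the measure's arithmetic, not the biology.

## Problem sizes and numerical choices

The standard study conditions are desk-scale: 100-neuron populations,
2.5-4 s of simulated time per sweep cell (500 ms transient discarded),
3 trials for trial-averaged quantities, detuning grids of five values
(+-0.4 uA/cm^2) by six delays (0.5-9 ms), and 9 x 12 grids for the
phase-model maps.  The dense grids behind the CLI's `--full` flag
reproduce the full parameter planes at correspondingly higher cost.  Delays
are rounded to the 0.01 ms integration grid (with a warning when rounding
changes the value) and enter per-edge ring buffers; a delay of zero is
promoted to one step so that spike delivery never races ahead of
detection.  Durations are snapped to the step grid with floor(x + 0.5) so
the R and compiled layers agree on step counts.

## Limitations

The networks oscillate in a single (gamma) band at high coherence; slow
synapse types, multi-band dynamics and low-coherence regimes are out of
scope, as are distance-dependent connectivity and delay distributions (a
single scalar delay per projection).  The phase reduction assumes weak
coupling, near-sinusoidal collective response and locking; its predictions
are compared with simulations only inside (or near) the locking zone.  The
ZLC of the slow-signal experiments inherits the large sampling variance of
covariances between slowly varying series — at desk-scale durations only
its paired cell-to-cell comparisons, not single values, are meaningful.
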