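---
title: "Criticality in the stochastic Wilson-Cowan model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criticality in the stochastic Wilson-Cowan model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochwc)
```

## The model

`stochwc` studies a stochastic two-population Wilson-Cowan network: `N`
excitatory and `N` inhibitory neurons, each a two-state Markov unit that is
either active or quiescent. An active neuron deactivates at rate `alpha`
(ms^-1); a quiescent neuron activates at rate `f(s)`, where

* `s = (w_E k - w_I l)/N + h` is the common synaptic input (`k`, `l` the
  active counts, `h` a small external drive),
* `f(s) = beta * tanh(s)` for `s > 0` and `0` otherwise.

All rates are in ms^-1 and `s` is dimensionless (membrane potentials are
measured in units of 1 mV, so the weights absorb the millivolt scale). The
per-neuron instantaneous firing rate is `R = (1 - (k + l)/(2N)) f(s)`;
pooled over both populations the expected spike count in `dt` is `2 N R dt`.

The control parameter is the net coupling `w0 = w_E - w_I`. In the
infinite-`N` limit the mean activity `Sigma = (k + l)/(2N)` relaxes to a
fixed point `Sigma0` solving `alpha Sigma0 = f(w0 Sigma0 + h)(1 - Sigma0)`.
For `h = 0` the quiescent state `Sigma0 = 0` loses stability at
`w0c = alpha/beta`, and the fixed-point firing rate
`R0 = (1 - Sigma0) f(w0 Sigma0 + h)` behaves as a continuous order
parameter: zero below `w0c`, growing linearly just above. The relaxation
times `tau1` (slow, mean activity) and `tau2` (fast, excitation/inhibition
imbalance) follow from the Jacobian; `tau1` diverges as
`1/(beta |w0 - w0c|)`, the model's critical slowing down.

## Layers of the package

**Deterministic layer** (`wc_params`, `solve_fixed_points`,
`relaxation_times`, `critical_coupling`): closed forms plus bracketed
root-finding (Brent, tolerance 1e-12) on the full `tanh` activation. The
near-threshold quadratic approximation is never used for reported values;
it only motivates the stability classification. Unstable roots are
reported with `stable = FALSE` so the stability exchange at `w0c` is
testable.

**Linear-noise layer** (`wc_linear_noise`, `correlation_matrix`,
`rate_statistics`, `rate_autocorrelation_analytic`): the system-size
expansion around the attractive fixed point gives a linear
Ornstein-Uhlenbeck pair for the fluctuations of `Sigma` and of the
imbalance `Delta = (k - l)/(2N)`, with triangular drift (the imbalance
feeds forward into the mean activity with strength
`w_ff = (1 - Sigma0)(w_E + w_I) f'(s0)` but not conversely). The
stationary covariance is computed twice -- numerically from the Lyapunov
equation and from the closed form -- and the constructor refuses to return
if they disagree beyond 1e-10. Time correlations use the explicit
two-exponential matrix exponential, with a dedicated branch when
`|1/tau1 - 1/tau2| < 1e-12` ms^-1 (where the off-diagonal term becomes
`w_ff t exp(-t/tau1)`). The firing-rate statistics expose both the
normalised variance `sigma_RR = N Var(R)` (ms^-2) and the squared
coefficient of variation `cv2 = sigma_RR / R0^2` under separate names:
the latter is the quantity that reaches ~6, ~2.4e3 and ~4.6e7 at
`w0 = 1, 0.2, 0.1` (`h = 1e-5`, `w_E + w_I = 13.8`) and sets the system
size below which dynamics is avalanche-like rather than Gaussian.

**Simulation engines** (`wc_gillespie`, `wc_langevin`): the exact engine
simulates the continuous-time Markov chain with the Gillespie algorithm.
Because the all-to-all neurons within a population are exchangeable, the
default engine lumps the state to `(k, l)` with four channels at rates
`alpha k`, `(N - k) f(s)`, `alpha l`, `(N - l) f(s)` -- an exact O(1)
per-event reformulation that reaches `N = 1e6` on one core; a literal
per-neuron implementation is retained and shown statistically equivalent
in the tests. The Langevin engine integrates the chemical Langevin
equations (drift `-alpha k + f(s)(N - k)`, demographic noise
`sqrt(alpha k + f(s)(N - k))`) by Euler-Maruyama at `dt = 1e-3` ms.
Negative noise arguments are clamped at zero before the square root and
the state is clamped to `[0, N]` after each step; clamping preserves the
drift and is the standard boundary treatment for chemical Langevin
equations. With `h = 0` the all-quiescent state is absorbing and the
simulator legitimately idles to `t_max` (flagged, not an error).

Stationary statistics are accumulated exactly (time-weighted over the
piecewise-constant trajectory) after discarding a burn-in of
`20 max(tau1, tau2)` by default, starting from `(k, l) = round(N Sigma0)`.
Randomness flows through R's generator (`set.seed`), shared with the
compiled code via the standard RNG scope, and the seed is recorded in
every result object.

## Avalanche analysis

Two detectors implement the two standard avalanche definitions:

* **Time-binned** (`detect_binned`): an avalanche is a maximal run of
  consecutive `delta`-bins each containing at least one spike (spike =
  activation of either population; deactivations never count). Size is
  the spike count; duration is the bin count times `delta`. Bins are
  anchored at `t = 0`. The engine can histogram spikes into bins online so
  `N = 1e6` runs need not store events.
* **Threshold** (`detect_threshold`, and `exact_threshold_catalog` for
  event-resolution excursions recorded online by the engine): an
  avalanche is a maximal excursion of `R(t)` strictly above a threshold
  `Theta`; sizes are either spike counts (definition 1), the integrated
  rate (2), or the integrated excess rate (3). Definitions 2 and 3
  coincide at `Theta = 0`.

Integrated sizes are reported in Hz x ms (`size_scale = 1000`), the
working units of the rate signal; with per-population size `N` this equals
`N/1000` expected spikes per unit. This convention is what makes the
conventional lower fitting bound `S_min = 10` sit at the start of the
scale-free tail for `N ~ 1e6`; spike-count units are one argument away
(`size_scale = N`).

Exponents are estimated by maximum likelihood on raw values, never on
binned histograms: the continuous closed form
`tau = 1 + n / sum(log(x/xmin))` for real-valued sizes and durations, and
the discrete zeta-normalised likelihood (Hurwitz zeta via Euler-Maclaurin
summation, 15 explicit terms plus four correction terms, accurate to
~1e-13) for integer data. The asymptotic standard error is
`(tau - 1)/sqrt(n)`; fits with fewer than 50 tail samples are flagged. An
`xmin` sweep reproduces the lower-bound sensitivity analysis; the
Kolmogorov-Smirnov distance of the fitted tail is always reported.

`size_duration_scaling` fits `log <S|T>` against `log T`. With desk-scale
catalogs the counts per distinct duration in the upper scaling window are
small and heteroscedastic, so a count-weighted fit is available alongside
plain least squares. `avalanche_shape` averages per-bin spike counts at
rescaled time `t/T` and rescales by `T^(1 - gamma)`; collapse quality is
the common-grid variance across duration classes normalised by the squared
mean curve.

## Correlation analysis

`empirical_autocorrelation` estimates the normalised stationary
autocorrelation by FFT with the plug-in variance (biased but stable at
long lags), and attaches per-lag standard errors from 20 non-overlapping
batch means. `fit_correlation_time` extracts the maximum correlation time
as `-1/slope` of `log C` over the lags whose correlation lies inside a
value window, by default `[0.01, 0.2]` of the peak -- the long-time tail.
`integrated_correlation_time` sums the correlation over the lags that are
individually significant (3 standard errors); it is the robust summary
for records whose far tail sits below the noise floor, and is what the
trend tests use.

## Synthetic ground truths

Every estimator is validated against generators with known answers,
independent of the Wilson-Cowan machinery:

* **Critical branching process** (`branching_avalanches`): Galton-Watson
  avalanches with Poisson offspring (any finite-variance offspring law
  shares the critical exponents). At branching ratio `m = 1` the size and
  duration tails have exponents 3/2 and 2 -- the mean-field branching
  universality class the model's avalanches are tested against.
  Durations are capped at 1e4 generations; at `m = 1` the truncated
  fraction is of order 1e-4 and sits far beyond every fitting window.
  The duration tail carries `1/t` pre-asymptotic corrections, so its
  discrete MLE reaches 2.00 only for lower bounds near 100 generations;
  the calibration test fits there.
* **Ornstein-Uhlenbeck process** (`ou_series`): exact discretisation,
  started in stationarity; autocorrelation exactly `exp(-t/tau)`. Its
  threshold excursions give the first-passage null exponents (durations
  3/2, excess areas 4/3) that finite-threshold avalanche detection
  must reproduce -- and that distinguish a thresholding artefact from
  genuine branching-process scaling.
* **Power-law samplers** (`powerlaw_samples`): inverse-CDF for continuous
  samples; for discrete samples, exact inversion of the zeta survival
  function (bulk CDF table plus integer bisection on the Hurwitz-zeta
  survival in the far tail).
* **Master equation** (`master_equation_stationary`): for `N <= 6` the
  full `(N+1)^2`-state generator is solved directly for its stationary
  law, giving a brute-force oracle for the Gillespie engine (the suite
  requires total-variation agreement below 0.01 at `N = 3`).

## Study conditions and problem sizes

The package's reference conditions are `alpha = 0.1` ms^-1, `beta = 1`
ms^-1, `w_E + w_I = 13.8`, with the three operating points `w0 = 1`
(deep in the active phase), `w0 = 0.2` (active, near-linear) and
`w0 = 0.1 = w0c` (critical), and external drives `h` between 1e-6 and
1e-2. The test-suite and acceptance problem sizes are chosen for a single
core: the near-critical avalanche analysis runs at `N = 1e6` for 1e6 ms
(about 2e9 Markov events), one decade below the largest sizes used to
establish the original scaling picture; the mean-rate check runs at
`N = 1e3` for 1e7 ms; correlation trends use `N` up to 1e6 with records
of 1e5-1e6 ms. At this scale the avalanche-size MLE at `S_min = 10`
(integrated-rate units) reads about 1.58 against 3/2 asymptotically --
the residual is the finite cutoff, and it shrinks visibly as `N` or the
lower bound grows (the `xmin` sweep in the tests shows 1.50 at
`S_min ~ 1e3` spikes).

## Design decisions worth knowing

* **Scaling window for `gamma` at reduced `N`.** The size-duration
  exponent is fitted over durations 50-150 ms at `N = 1e6`. The
  conventional 80-200 ms window was established at `N = 1e7`; at
  `N = 1e6` its upper half lies in the cutoff and holds only a few
  hundred avalanches, which depresses the slope and makes it seed-noisy
  (~1.8-2.1 there vs a stable ~2.07-2.09 in the pre-cutoff window). A
  count-weighted fit is available for small-count windows.
* **Downstates at small drive.** At `h <= 1e-5` the network occasionally
  falls into near-quiescent epochs whose escape time scales like
  `1/(N f(h))`. These excursions are genuine (the exact engine shows
  them as clearly as the Langevin surrogate) and they add a slow,
  non-linear component to the rate autocorrelation that the linear-noise
  solution does not describe. Agreement between the analytic and
  empirical correlation functions at `w0 = 0.2` is therefore tested at
  `N = 1e6`, where the excursions are absent over desk-scale records;
  at `N = 1e5` the contamination is visible and expected.
* **Imbalance bias.** The mean imbalance `<Delta>` is zero only in the
  infinite-`N` limit; the exact process has a systematic negative O(1/N)
  bias (about `-1.6/N` at `w0 = 0.15`) because `f(s)` covaries
  positively with `Delta`. The balance test asserts the 1/N decay, not
  zero-within-noise.
* **Finite-size convergence of `<Sigma>`.** Convergence to `Sigma0` with
  growing `N` is only monotone once `N` exceeds roughly the squared
  coefficient of variation; below that the mean activity is strongly
  suppressed and non-monotone in `N`. Tests therefore probe `N` in
  {1e3, 1e4, 1e5} at `w0 = 0.2, h = 1e-3` (and the tiny-`N`
  master-equation check runs at strong drive).
* **Trend statistics.** Correlation-time growth with `N` (and decay with
  `h`) is asserted on the integrated correlation time; the
  exponential-tail fit is reserved for curves whose tail is resolved
  (analytic curves, OU fixtures, large-`N` runs).
* **What the fixtures do not emulate.** The generators validate
  estimators, not biology: no refractoriness, no spatial structure, no
  synaptic dynamics. Passing tests demonstrate that the estimators
  recover known exponents and that the engines simulate this model
  exactly -- not that cortical recordings obey these statistics.

## A worked analytic example

```{r analytic}
p <- wc_params(w0 = 0.2, w_sum = 13.8, h = 1e-3, N = 1e4)
stable_fixed_point(p)$r0_Hz      # fixed-point rate, Hz
sol <- wc_linear_noise(p)
rate_statistics(sol)$cv2         # squared coefficient of variation
critical_coupling(p)             # alpha/beta
```

```{r simulate, eval = FALSE}
# a short stochastic run (a few seconds)
sim <- wc_gillespie(p, t_max = 5e4, seed = 1, record = "series")
sim$moments$mean_rate_Hz
ac <- empirical_autocorrelation(sim$series, max_lag = 200)
fit_correlation_time(ac, window = c(0.05, 0.5))$tau_max
```

## Known limitations

* Asymmetric weights (`w_EE != w_IE`, ...) and unequal population sizes
  are out of scope; the 20%-inhibitory variant of the shape analysis is
  not implemented.
* The Langevin integrator is fixed-step Euler-Maruyama; its variance
  carries an O(dt) positive bias (a few percent at `dt = 1e-3` ms in the
  regimes used here). Where exactness matters the Gillespie engine is
  authoritative.
* Threshold crossings are located at sample resolution in
  `detect_threshold`; the event-resolution path (`record = "avalanches"`)
  avoids the bias entirely for Gillespie runs.
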