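---
title: "Effective astrocytes: from cleft-scale diffusion to network synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective astrocytes: from cleft-scale diffusion to network synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

astronet links two scales of modelling. At the microscale, a Monte-Carlo
simulation of neurotransmitter diffusion in an idealized synaptic cleft
quantifies how deeply-protruding astrocyte processes change a synapse's
transmitted signal. At the network scale, the resulting linear "effective
astrocyte" rule is applied synapse-by-synapse to balanced networks of
exponential integrate-and-fire (EIF) neurons to study when ensheathment
breaks excitation-inhibition balance and drives synchrony. This vignette
documents the models, the assumptions, the numerical choices, and the
limits of what the package's simulations can show.

## 1. The microscale model

The cleft is a 2D rectangle of width `c_w = 1` and height `c_h = 0.1`
(arbitrary units). `n_nt = 1000` neurotransmitter molecules are released
at the top-center `(c_w/2, c_h)` and perform independent Brownian steps
with per-axis standard deviation `sqrt(2 * d_coef * dt_diff)`. The bottom
boundary carries `n_rec = 50` equal receptor segments on the postsynaptic
density `[0.25, 0.75]`. A molecule crossing the bottom inside a receptor
segment is captured with probability `k_abs * sqrt(pi * dt_diff /
d_coef)` — the standard Robin-boundary discretization for a partially
absorbing surface in particle simulations: it is dimensionless,
proportional to `sqrt(dt)`, and converges to absorption rate `k_abs` as
`dt_diff -> 0`. A capturing receptor becomes *active* and reflects for an
exponentially distributed recharge time (mean `tau_r = 0.1`), after which
it absorbs again. Two astrocyte walls at `x = c_w * phi/2` and
`x = c_w * (1 - phi/2)` absorb on first contact; `phi` in `[-1, 0.95]` is
the fraction of the cleft blocked. For `phi < 0` the walls lie outside
the cleft, and the gap between each cleft mouth and its wall is an
extracellular pocket wrapped by the astrocyte flush along the terminal
membranes: the pocket keeps the cleft's height, its outer wall and
ceiling absorb, its floor reflects. This geometry was chosen over a
simple widened strip (reflecting top and bottom everywhere) because the
strip makes the capture statistics grow steadily with wall distance —
residence time over the receptors increases quadratically with the
domain half-width — whereas the wrapped pocket makes escape through the
cleft mouth depth-independent once the gap exceeds the cleft height.
Only the pocket geometry reproduces the observed plateau below
`phi ~ -0.2`, and it places the breakpoint naturally at the protrusion
where the gap equals the cleft height (`0.1 * c_w` here).

The synaptic time course is the number of active receptors over time; its
area (trapezoidal rule) is the synaptic *strength* and the total time at
or above half the peak (crossings located by linear interpolation, summed
over multiple excursions, on a curve binned at 0.05 time units) is the
*half-max width*. Sweeping `phi` over `[-1, 0.95]` produces a plateau for
`phi` below about `-0.2` — the astrocyte is too far away to compete with
the receptors — followed by a near-linear decrease to zero as the
astrocyte fills the cleft. `fit_piecewise_linear()` captures this with a
continuous plateau-then-line least-squares fit, scanning candidate
breakpoints on the data grid and refining between neighbors.

Numerical choices: `dt_diff = 1e-5` keeps the rms step below a quarter of
the cleft height (enforced at construction); the time cap is 200 units
and particles still free at the cap are tallied separately so particle
conservation is checkable; reflection is specular, unbiased to
`O(sqrt(dt))`.

## 2. The effective astrocyte

Across the sweep, both strength and width fall linearly with protrusion
beyond the breakpoint. The network model therefore represents an
ensheathed synapse by scaling both its weight and its synaptic time
constant: `J -> J * (1 - s_en)`, `tau -> tau * (1 - s_en)`, with
`s_en` in `[0, 1)` the ensheathment strength. Each recurrent synapse with
an excitatory (inhibitory) presynaptic neuron is independently ensheathed
with probability `p_e` (`p_i`); feedforward projections are never
ensheathed. Because the synaptic kernel `eta(t) = (1/tau) exp(-t/tau)`
integrates to 1 for every `tau`, the `tau` scaling changes only kinetics
— an ensheathed synapse is *faster* — while the `J` scaling makes it
*weaker*. The dissociation variants (`mode = "j_only"`, `"tau_only"`)
scale one parameter only, over the identical flagged synapse set (the
assignment depends only on the ensheathment seed), making the comparison
controlled. `s_en` stays below 1 so that connections are never removed
and the dense-connectivity regime is preserved.

A naive mean field would replace the heterogeneous network by a
homogeneous one with every synapse scaled by `s_en * p_e`
(`naive_mean_field_strength()`). The package exposes this comparator
because the heterogeneous and homogeneous networks behave differently
along isolines of `s_en * p_e` — the failure that motivates per-synapse
modelling.

## 3. The EIF balanced networks

Membrane dynamics follow
`dV/dt = -(V - E_L)/tau_m + (Delta_T/tau_m) exp((V - V_T)/Delta_T) + F(t) + R(t)`
with spike at `V_th = -10` mV, reset to `V_re = -65` mV, and a
population-specific refractory hold. Recurrent input is
`R_j = sum_k (J_jk / sqrt(N)) (eta_jk * S_k)(t)` — the strong-coupling
`1/sqrt(N)` scaling under which the reference weights (tens of mV)
produce order-one inputs, recurrent inhibition dynamically tracks and
cancels excitation, and firing stays irregular. The non-spatial graph
fixes the *out*-degree: every neuron of population `b` sends exactly
`k_out[a, b]` edges to uniformly chosen distinct targets in population
`a`. The feedforward drive is a static bias `sqrt(N) * m_a` plus a shared
Gaussian process `sigma_s * s(t)` with autocovariance
`exp(-tau^2 / tau_s^2)`, either one realization for the whole network or
two independent realizations for randomly split halves. The spatial
variant places neurons on grids over the unit torus, draws contacts from
wrapped-Gaussian displacement profiles (width `alpha_rec` recurrently,
`alpha_ffwd` for a Poisson-spiking feedforward layer), and keeps the same
fixed out-degree per projection.

Implementation notes, in decreasing order of consequence:

- **Class-based synaptic filtering.** With a single global `s_en` there
  are at most four recurrent kernel classes per neuron (source population
  x ensheathment state), plus one feedforward class, so the per-synapse
  heterogeneity costs five exponential filter states per neuron rather
  than one per synapse. A presynaptic spike increments the target's class
  state by `j_eff / (tau_class * sqrt(N))`.
- **Exact discrete charge.** Filters decay by the forward-Euler factor
  `(1 - dt/tau)` per step, under which the discrete time-integral of one
  spike's input is *exactly* `j_eff / sqrt(N)`, independent of `tau` —
  so `tau`-only ensheathment conserves per-spike charge to machine
  precision and `J`-only scales it by exactly `1 - s_en`.
- **Integration.** Forward Euler at `dt = 0.05` ms; spikes detected at
  step end; membrane potential clamped at `V_th` inside the exponential
  to avoid overflow; the exponential is evaluated from a dense lookup
  table with linear interpolation (relative error below `4e-6`); spikes
  delivered with effect from the following step. Halving `dt` leaves
  population rates within a few percent.
- **Noise generation.** The squared-exponential process is white noise
  circularly convolved with a Gaussian kernel of standard deviation
  `tau_s / 2` (its self-convolution then has exactly the target width)
  and normalized by the exact discrete kernel power, giving unit variance
  and the stated autocovariance on the sample grid.
- **Initial conditions.** `V(0) ~ U[V_re, V_T]` per neuron under a
  dedicated seed, and the synaptic filter states start at their
  mean-field stationary values (computed from the balance-equation rates
  of the parameter set; zero if that system is singular or has no
  positive solution). Starting the filters at zero under full drive
  leaves the network transiently without recurrent inhibition, and at
  desk scales that onset transient can lock otherwise-asynchronous
  realizations into a volley state within the first ~50 ms. A linear
  drive ramp was evaluated for the same purpose and rejected: under a
  slow ramp the membrane dynamics contract all voltages onto the common
  quasi-equilibrium trajectory faster than the drive rises, so the whole
  population crosses threshold together — worse than an instantaneous
  onset. The first 500 ms are discarded from every analysis regardless.
- **Runaway guard.** A spike budget (default: 60 Hz network-average)
  stops runs whose spike count implies runaway excitation; such runs are
  flagged `truncated` and treated as unstable/synchronous outcomes, never
  silently dropped.
- **Feedforward calibration (spatial model).** The feedforward weights
  `J_eF = 140`, `J_iF = 100` mV and out-degrees `K_eF = 12000`,
  `K_iF = 1400` are calibration constants of this package. The weights
  follow the convention of the non-spatial weights' magnitude; the
  out-degrees are then set so the mean feedforward drive, in-degree
  `* J_aF/sqrt(N) * r_F`, places the default spatial network's excitatory
  rate near 5 Hz (comparable to the non-spatial model's balance solution).
  A weaker drive leaves the network firing below 2 Hz, where the recurrent
  interactions are too weak to express any of the spatial correlation
  structure. Both constants are exposed as ordinary configuration fields.
- **Reproducibility.** All compiled-code randomness uses a 64-bit
  Mersenne Twister with hand-rolled normal/exponential transforms
  (standard-library distributions are implementation-defined), so a seed
  chain fully determines a run; `derive_seed()` hashes (master seed,
  experiment, cell, realization) into independent streams.

## 4. Analyses

- `spike_count_correlations()`: Pearson correlations of spike counts in
  non-overlapping 250 ms windows (the convention of the balanced-network
  literature; the window is exposed). Pairs with a zero-variance count
  vector are excluded and reported, not zero-imputed. Within/across
  breakdowns use the drive groups; distance-resolved versions bin pairs
  by torus distance.
- `classify_synchrony()`: the population rate in 2 ms bins, smoothed with
  a Gaussian kernel (sigma = 5 ms), is summarized by its peak-to-mean
  ratio. Asynchronous balanced firing keeps this index below about 2;
  full-population volley states sit above 6 — but not dramatically
  higher, because inhibitory neurons spike several times per volley and
  inflate the mean, capping the index of unambiguous synchrony near 7.
  The default threshold is therefore 4, the midpoint of the observed
  separation, calibrated on reference-scale simulations and exposed as a
  parameter. Workbench protocols additionally count spike-budget
  truncation (runaway excitation) as a synchronous outcome.
- `shared_current_decomposition()`: component-wise population averages of
  recorded input currents, Gaussian-smoothed (sigma = 15 ms), mean
  subtracted, and divided by the population rheobase
  `(V_T - E_L - Delta_T)/tau_m` (8/15 mV/ms for the excitatory
  population). In the balanced state the recurrent trace mirrors the
  feedforward trace and their sum stays small.

## 5. What the desk-scale experiments can and cannot show

The workbench's `scale` knob multiplies population sizes and out-degrees
(keeping weights fixed, so the `1/sqrt(N)` normalization adapts) and is
how the figure-level protocols run in minutes instead of hours. Two
properties of the model degrade gracefully but genuinely under scaling,
and the package documents rather than hides them:

- **Finite-size synchronization.** The asynchronous balanced state of the
  default non-spatial network is a large-`N` phenomenon: at reference
  size (N = 20,000) the default network fires irregularly (synchrony
  index near 1), but population-sized fluctuations grow as `1/sqrt(N)`
  and below roughly half the reference size they are strong enough to
  entrain volley-like collective oscillations even without ensheathment.
  Protocols that hinge on the default network being asynchronous are
  therefore run at the smallest scale that robustly preserves the
  asynchronous default across 10-realization batteries — scale 0.8
  (N = 16,000) for the one-population synchrony, dissociation, and
  balance protocols. The two-population correlation structure is carried
  by the competing drive groups and survives at scale 0.2, where those
  protocols run; the spatial protocols run at 0.25. At scale 0.6 roughly
  one default realization in twenty is still tipped into volleys by a
  deep (~4 sigma) excursion of the shared feedforward process — the same
  loss-of-balance mechanism that ensheathment makes routine, acting on
  the reduced finite-size margin.
- **Stochastic onset.** Ensheathment-driven loss of balance is triggered
  by excursions of the shared feedforward process, so whether a given
  5-second realization synchronizes depends on the noise seed — at
  moderate ensheathment the reference-scale model is
  bistable-in-practice. Fractions over realizations, not single runs,
  are the meaningful statistic.

The synthetic fixtures (`generate_fixture()`) exercise every analysis
path without the simulator: Poisson rasters (null correlations,
asynchrony), volley rasters (synchrony), two-group rasters with
antiphase rate envelopes (within-positive/across-negative correlations),
and noiseless plateau-then-line curves (fit recovery). They emulate the
statistical structure the analyses target, not the biophysics — passing
them validates the analysis code, not the network model.

## 6. Known limitations

The cleft model is 2D with a single recharge state per receptor and no
explicit transporter kinetics; the network model has current-based
synapses, no adaptation, no synaptic delays, and a single global `s_en`.
Extensions such as per-synapse ensheathment distributions, time-varying
ensheathment, or synapse pruning are deliberately out of scope.
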