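---
title: "Methods: synthesizing spiking networks with spatiotemporal tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthesizing spiking networks with spatiotemporal tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neftools)
```

This vignette records the modeling assumptions behind `neftools`, the
defaults we chose where the underlying theory fixes none, the numerical
decisions that matter for reproducing results, and the known limitations of
the synthetic-data experiments.

## 1. The tuning-curve model and its assumptions

Every population is a set of leaky integrate-and-fire (LIF) neurons with a
linear-nonlinear tuning curve: neuron $i$ responds to a represented value
$x$ with rate $G[\alpha_i \langle e_i, x\rangle + \beta_i]$, where $G$ is
the closed-form LIF rate (zero below the unit threshold current,
$1/(\tau_{ref} + \tau_{rc}\ln(1/(1 - 1/J)))$ above it).  The membrane and
refractory constants default to $\tau_{rc} = 20$ ms and $\tau_{ref} = 2$ ms
— the standard values in this modeling tradition; both are arguments of
`lif_params()`.  Rate surrogates (ReLU, sigmoid) are available wherever a
spiking model is not needed.

Tuning parameters are sampled, not fitted: maximum rates uniform in
100–200 Hz and onset intercepts uniform in $[-1, 1)$ by default, inverted
through $G$ by `solve_gain_bias()`.  Two deliberate exceptions use
200–400 Hz: the oscillator populations of the path and temporal integrators,
where the error budget is dominated by filtered spike noise accumulating
through a (marginally stable) recurrent loop, and doubling the rates
roughly halves that noise.

*Temporal* tuning replaces the encoder with a kernel over stimulus lags.
Kernels are stored as samples on a lag grid with the simulation step as
spacing, inner products use trapezoidal weights, and kernels are
L2-normalized on the window by default (`set_temporal_encoders(normalize =
TRUE)`); normalization is exposed as a flag because nothing in the theory
forces it — it simply makes intercepts comparable across neurons.  Kernels
exist only for nonnegative lags, which is what enforces causality.

The key assumption inherited by everything downstream: **the weight solver
treats the desired tuning as already realized** ("self-fulfilling
prophecy").  Solutions are locally optimal only; all the network-level
guarantees in the tests are empirical, not theorems.

## 2. Weight solving

`solve_weights()`/`solve_decoders()` perform ridge regression of (filtered)
presynaptic activity onto the currents demanded by the postsynaptic tuning
at $f(x)$, sampled at `N = 500 * dim` points uniform in the represented
ball.  The ridge scale defaults to `reg = 0.1` times the maximum activity,
entering the Gram matrix as $N\sigma^2$.  That default trades decode
accuracy for noise robustness; the path integrator lowers it to 0.02 (see
section 5).  For exponential synapses, dynamical systems bypass the
time-sampled solve via the low-pass compensation $(\tau A + I, \tau B)$
(`map_lti_through_lowpass()`); `solve_temporal_weights()` is the general
path — probe signals (32 band-limited noise signals of length $4\theta$ by
default) are pushed through the desired temporal encoders to get target
currents over time, and recurrent plus input weights are fit on a uniform
time grid over the probes, after a one-window burn-in.  The set of
evaluation times is our reconstruction; the underlying description evaluates
filtered activity "at the present moment" without fixing a sampling scheme.

## 3. Temporal bases and time cells

`make_ldn()` uses the closed-form state matrices
$A_{ij} = (2i+1)/\theta \cdot (-1 \text{ if } i<j, (-1)^{i-j+1} \text{
otherwise})$, $B_i = (2i+1)(-1)^i/\theta$; the $q = 1$ case reduces to the
$[0/1]$ Padé approximant of a pure delay, which the tests verify.  Delay
readout weights are the shifted Legendre polynomials evaluated at
$\theta'/\theta$ — we validated this convention numerically against
least-squares-optimal readouts rather than trusting transcription.  Two
honest caveats frozen into the tests: impulse-response components match
shifted Legendre polynomials closely only at low order (correlations
0.97/0.94/0.90/... at $q = 7$), and delay reconstruction quality depends
strongly on the product of window length and signal bandwidth (essentially
exact at $\theta f \le 1.5$ with $q = 7$; the monotone improvement with $q$
is tested at $\theta f = 2.5$).

The Modified Fourier system is a reconstruction: one low-pass mode plus
harmonic oscillator pairs at $k/\theta$, with a uniform damping parameter
(default $1/\theta$) because no damping value is fixed by the sources we
implement from.  Its dynamics matrix family is shared with the temporal
integrator of section 6.

`run_time_cell_experiment()` builds time cells the principled way: the
population represents the LDN state, recurrent weights realize the LDN
through the synapse, and each neuron's state-space encoder is the delay
readout at its assigned delay $\theta_i$, making its temporal tuning a bump
at $\theta_i$.  Delays follow $\theta_i = \theta U^{1.5}$ (biased short),
50% of neurons are "off"-neurons with negated encoders, and intercepts are
drawn from $[0, 0.4]$ so roughly half the on-neurons respond to a unit
pulse.  The representation radius is set from the ideal pulse response
(1.2 times its peak norm) — the normative trajectory is known, so sizing
the representation to it is part of the synthesis, not a fit to test
outcomes.

## 4. Spatial Semantic Pointers

`ssp_space()` builds the conjugate-symmetric phase matrix with one
zero-frequency row, guaranteeing real, exactly unit-norm encodings.  For
1-D random spaces the free phase slopes are a *stratified* (jittered-grid)
sample of the uniform density on $[-\pi, \pi]/\ell$: the limiting sinc
kernel is identical to iid sampling, but the Monte-Carlo ripple drops by an
order of magnitude (sup-norm error vs sinc ~0.006 at $d = 301$ instead of
~0.08), which is what makes the kernel-level claims testable at moderate
dimension.  Higher-dimensional random spaces sample iid uniform; hex spaces
(for grid cells) build plane-wave triplets 120° apart across five
geometrically spaced scale modules and five orientations (module counts are
our choice; the biology fixes the organization, not the numbers).

The default `length_scale = 0.5` spatial units defines the kernel width.
Map queries use raw dot products, not cosine similarity, since pure
encodings are unit-norm and map sums are deliberately not renormalized;
region integrals use a rectangle rule at `length_scale/4` spacing without
area normalization (a `normalize` flag exposes the density convention).
The rectangle rule on a polygon converges first order in the spacing
(boundary cells), which the tests assert as such.  `ssp_decode()` is a
coarse grid argmax refined by BFGS on the Fourier-domain similarity, with a
0.25-similarity reliability threshold.

## 5. Path integration

The ideal integrator advances each frequency component's phase by
$a_j \cdot \dot x \, dt$ per step — exactly unitary, so constant velocity
reproduces direct encoding to machine precision.

The spiking integrator assigns one 3-D population per conjugate frequency
pair, representing (Re, Im, projected velocity), with all pairs sharing
tuning and decoders; recurrent decoders realize the velocity-controlled
rotation (a nonlinear product) through the low-pass compensation.  Two
additions proved necessary and are defaults:

- a **unit-circle limit-cycle term** ($\kappa = 5$/s) in the recurrent
  function: the phasor radius is neutrally stable, and filtered spike noise
  otherwise random-walks it away from 1 over tens of seconds;
- **bias calibration of the rotation**: decoders are trained on the
  operating manifold (radius 0.8–1.2 ring at all represented velocities,
  `reg = 0.02`), the residual tangential decode bias is measured around the
  ring in the rate model, and a counter-rotation is added to the target
  before a second solve.  Any uncancelled tangential bias is a frequency
  offset that integrates into unbounded phase drift; calibration reduces it
  from ~0.2 to ~0.015 rad/s, after which a 60 s, 180 cm-arena run tracks
  with sub-centimetre median error at 500 neurons per oscillator.

The foraging trajectories are synthetic smooth random walks
(`gen_trajectory_2d()`: low-pass-filtered white-noise velocity reflected at
the arena wall, 20 cm/s mean speed, 60 s in a 180 cm circular arena by
default).  Real rodent paths have pauses, wall-following and head-direction
statistics these walks lack, so passing tests show the integrator tracks
smooth self-motion — not that it handles behavioral intermittency.

## 6. Trajectory memory

`temporal_integrate()` steps each Fourier coefficient by an exact rotation
at its time-frequency plus an Euler accumulation of the input encoding, so
it matches brute-force quadrature of the memory integral to rounding.  The
time-phase vector uses its own length scale (default examples use 0.3 s).
The spiking realization is one linear 2-D oscillator population per
frequency pair (plus a scalar accumulator for the zero-frequency term),
each with its own representation radius taken from the ideal coefficient
envelope times 1.25 — the normative trajectory is an input to the synthesis
here, exactly as in section 3.

A deliberate divergence from expectation: with exact stepping the
similarity-profile width around the ridge is *constant* in lag
(shift-invariant kernels), and the spiking network adds only slight
widening at the oldest lags.  Accounts in which old memories blur
substantially imply heavier degradation than this realization exhibits; our
tests assert the ridge slope and the non-decreasing width trend, not strict
growth.  No forgetting is applied by default (`decay = 0`); a leak rate is
exposed for callers who want bounded memory norm.

## 7. Online learning

`pes_update()` is the delta rule on decoders, scaled by $1/n$ so rates are
population-size invariant.  The pendulum task feeds torque and a 50 ms
delayed angle into a 400-neuron population implementing two LDN systems
($q = 7$, $\theta = 0.5$ s) in one state space; inputs are normalized to
2.5 times their RMS, and the representation radius again comes from an
ideal pilot simulation of the first 20 s.  Pendulum physics defaults —
unit mass and arm, $g = 9.81$, viscous damping 1 N·m·s, 1 Hz band-limited
torque at 3 N·m RMS — were chosen once so the joint swings ±2 rad (strongly
nonlinear) without winding over the top; weaker damping lets the arm spin,
which both breaks the arm interpretation and trivializes prediction by
inflating the angle variance.  The default learning rate $2\times10^{-3}$
converges by roughly 120 s of the 200 s run; rates up to 16× larger remain
stable (`tune_learning_rate()` implements the doubling search) and land at
10–15% final error instead of ~18% — the result is insensitive within the
stable range.

The LLP (`llp_init()`/`llp_update()`) is our reconstruction of the learned
Legendre predictor: a coefficient matrix maps activities to shifted-Legendre
coefficients of the predicted window, and three LDN memories (activities,
prediction coefficients, observations) let the rule compare the present
observation against what was predicted for *now* across the stored past —
entirely through Legendre-basis evaluations, so the update is linear and
synapse-local.  We use a normalized-LMS step (fraction of error corrected
per unit time), which makes the learning rate dimensionless; rates ~2/s are
stable across the tasks here.  The ball experiment uses the `relative`
formulation (predict displacement over the window), under which straight-
line motion extrapolates exactly and the no-wall control converges to
~0.3% of the box.  The ball fixture's default velocity ratio is rational
(3:2), closing the orbit in 20 s: position-based context encodings can only
learn the motion when positions recur with consistent headings, which is
also why the position-only SSP context ends *below* the LDN context while
learning more slowly.  Known limitation: the LLP smooths what it stores;
its equilibrium predictions are biased toward recent history, and
performance is sensitive to the learning rate and memory orders.

## 8. Quasi-probability

`fit_quasi_density()` stores the mean of the encoded sample and corrects
the kernel similarity with the ReLU-with-offset rule.  Two numerical
choices: the quasi-value is scaled by $1/\ell^m$ before correction so it
matches the Fourier-integral (sinc-kernel) estimator whose role it plays —
without the scale the offset would have to flood the support with uniform
mass — and the normalisation offset $\xi$ is found by `uniroot` on a
quadrature grid (support = data bounding box padded by three length scales,
200 points per dimension).  The integral of the rectified density is
continuous and strictly decreasing in $\xi$ until it hits zero, so the
root is unique.  The corrected density is *not* the sinc KDE: negative
lobes are clipped and the offset subtracts mass, so agreement with the
brute-force estimator is asserted at the level of raw quasi-values, while
consistency (integrated absolute error shrinking with $n$) is asserted on
the corrected density.

## 9. Simulation engine and problem sizes

`network()`/`run_network()` execute inputs → filters → currents → neurons →
probes per step, at `dt = 1` ms by default, with spikes of amplitude
$1/dt$ so filtered trains estimate rates in Hz; exponential synapses use
the exact one-step recurrence and the LIF step locates threshold crossings
within the step, keeping long-run spike counts within a fraction of a
percent of the closed-form rate.  All randomness flows through R's seeded
generator; runs are bit-reproducible.

The test and experiment sizes are desk scale, chosen so the whole suite
exercises every claim in a few minutes of CPU: 100–400 neurons per
population, 60–240 s of simulated behavior, $d \le 401$ for vector
encodings, 200 s for the pendulum task.  Accuracy at these sizes is already
limited by spike noise and solver bias rather than by size, so scaling up
mainly buys smoother traces.
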