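# neftools

Functional spiking neural networks are hard to train end to end, but many of
the computations brains perform — holding a stimulus history, integrating
self-motion, storing a map of an environment, predicting the near future —
can be *synthesized*: decide what each neuron should be tuned to, declare the
transformation or dynamical system the represented variables should obey,
and solve a least-squares problem for the synaptic weights that make both
come true.  `neftools` implements that synthesis workflow (the Neural
Engineering Framework, generalized to spatiotemporal tuning) for
computational neuroscientists who want mechanistic, spiking models of time
cells, grid/place/border/object-vector cells, path integration, trajectory
memory, online motor prediction, and neurally represented probability.

## The model in brief

A leaky integrate-and-fire neuron fires at

    a_i(x) = G[ alpha_i <e_i, x> + beta_i ]

where `e_i` is its preferred direction (encoder), `alpha_i, beta_i` map
similarity to current, and `G` is the closed-form LIF rate response.
Replacing the static encoder with a temporal kernel `e_i(tau)` and the inner
product with an integral over the stimulus history gives *spatiotemporal*
tuning.  Given desired tuning and a target transformation `y = f(x)` (or
dynamics `x' = A x + B u`), connection weights solve the ridge-regularized
regression of filtered presynaptic activity onto the currents the
postsynaptic tuning demands; for exponential synapses a dynamical system is
realized by the recurrent transform `(tau A + I, tau B)`.

On top of the core solver the package ships:

- the **Legendre Delay Network** and **Modified Fourier** basis-generating
  LTI systems, delay decoding, and recurrent **time-cell networks**;
- **PES** online learning and a **learned Legendre predictor** (LLP) for
  multi-step prediction, with pendulum and bouncing-ball tasks;
- **Spatial Semantic Pointers**: `phi(x) = IDFT[exp(i A x)]`, binding by
  circular convolution (`phi(x) (*) phi(y) = phi(x + y)`), environment maps
  and similarity-map queries, grid/place/border/object-vector cell models
  with sparsity control;
- oscillator-based **path integration** and **temporal integration** of
  trajectories, both ideal and as recurrent spiking networks;
- **quasi-probability** densities: SSP-kernel density estimation with the
  ReLU-with-offset correction that restores nonnegativity and unit mass;
- a deterministic time-stepped **simulator** and seed-reproducible
  **synthetic fixtures** (pendulum, bouncing ball, arena random walks,
  drifting gratings).

## Worked example

Solve a connection computing `y = x^2` between two 100-neuron LIF
populations and simulate it spiking:

```r
library(neftools)
summary <- run_experiment("square", list(n = 100, duration = 2, seed = 1))
str(summary)
#> List of 2
#>  $ nrmse   : num 0.0795
#>  $ residual: num 0.475
```

`nrmse = 0.080` says the spiking network's decoded output tracks the
filter-matched target `x(t)^2` within 8% normalized RMSE; `residual` is the
RMS current residual of the weight solve (in units of threshold current,
against demanded currents spanning tens of those units).

The flagship experiment is the online pendulum prediction: torque and a
50 ms-delayed joint angle feed a 400-neuron recurrent population carrying
dual-LDN time-cell tuning, and the PES rule learns — from zero decoders —
to reconstruct the *current* angle:

```r
res <- run_pendulum_prediction(duration = 200, seed = 1)
res$nrmse_final
#> [1] 0.1815414
```

i.e. about 18% normalized RMSE over the final quarter of a 200 s run.
Other experiments (`timecells`, `gridcells`, `pathint`,
`trajectory-memory`, `llp-ball`, `kde`) run the same way through
`run_experiment()` or from a shell:

```sh
Rscript inst/cli/neftools.R timecells --seed 1 --out results/timecells
```

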