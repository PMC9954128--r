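#' Build and run a time-cell network
#'
#' Constructs a recurrent spiking population whose temporal tuning curves are
#' delayed bumps tiling a window: each neuron's encoder (in the LDN state
#' space) is the delay-readout vector at its assigned delay `theta_i`, so its
#' temporal encoder is the corresponding combination of LDN basis functions —
#' a bump peaked at `theta_i`.  Delays are biased toward shorter values, and
#' a configurable fraction of neurons are "off"-neurons (negated encoders
#' responding to negative input).  The recurrent weights realize the LDN
#' through the synaptic low-pass (`tau A + I`, `tau B`), and the network is
#' driven with a pulse; per-neuron filtered activities are returned together
#' with peak-time statistics.
#'
#' @param n number of neurons.
#' @param q LDN order.
#' @param theta window length (s).
#' @param off_fraction fraction of off-neurons (default 0.5).
#' @param delay_bias exponent of the delay law `theta_i = theta * U^bias`
#'   (bias > 1 concentrates delays near 0).
#' @param tau_rec recurrent synapse (s).
#' @param dt simulation step (s).
#' @param duration simulated time (s); default `2.4 * theta`.
#' @param pulse list(onset, width, amplitude) of the input pulse.
#' @param seed integer seed.
#' @return list: `t`, `activities` (T x n filtered rates), `thetas`,
#'   `off` (logical), `peak_times` (per on-neuron), `spearman` (rank
#'   correlation of peak time vs assigned delay over on-neurons), `pop`.
#' @export
run_time_cell_experiment <- function(n = 200, q = 7, theta = 0.5,
                                     off_fraction = 0.5, delay_bias = 1.5,
                                     tau_rec = 0.1, dt = 1e-3,
                                     duration = NULL,
                                     pulse = list(onset = 0.05,
                                                  width = 0.03,
                                                  amplitude = 1),
                                     seed = 1) {
  set.seed(seed)
  if (is.null(duration)) duration <- 2.4 * theta + pulse$onset
  ldn <- make_ldn(q, theta)
  thetas <- theta * stats::runif(n)^delay_bias
  off <- seq_len(n) <= round(off_fraction * n)
  E <- t(sapply(thetas, function(th) delay_readout(ldn, th)))
  E <- E * ifelse(off, -1, 1)
  # representation radius from the ideal pulse response
  u_fn <- function(t) {
    if (t >= pulse$onset && t < pulse$onset + pulse$width)
      pulse$amplitude else 0
  }
  n_steps <- round(duration / dt)
  u <- sapply((seq_len(n_steps)) * dt, u_fn)
  ideal <- lti_simulate(ldn, u, dt)
  radius <- 1.2 * max(sqrt(rowSums(ideal^2)))
  pop <- population(n, q, encoders = E, max_rates = c(100, 200),
                    intercepts = c(0, 0.4), radius = radius)
  Dx <- solve_decoders(pop, NULL, N = 2000,
                       signals = ideal[sample.int(n_steps, 1500,
                                                  replace = TRUE), ] *
                         matrix(stats::runif(1500 * q, 0.6, 1.4), 1500, q))
  tr <- map_lti_through_lowpass(ldn, tau_rec)
  net <- network(dt)
  net <- add_node(net, "u", function(t) u_fn(t))
  net <- add_ensemble(net, "cells", pop)
  net <- add_link(net, "u", "cells", transform = tr$Bp,
                  synapse = synaptic_filter("exponential", tau_rec))
  net <- add_link(net, "cells", "cells", decoders = Dx, transform = tr$Ap,
                  synapse = synaptic_filter("exponential", tau_rec))
  net <- add_probe(net, "cells", "rates",
                   synapse = synaptic_filter("exponential", 0.02))
  res <- run_network(net, duration, seed = seed)
  acts <- res$cells.rates
  # peak times of on-neurons relative to pulse onset
  on_idx <- which(!off)
  peak_times <- res$t[apply(acts[, on_idx, drop = FALSE], 2, which.max)] -
    pulse$onset
  active <- apply(acts[, on_idx, drop = FALSE], 2, max) > 5   # Hz
  sp <- stats::cor(peak_times[active], thetas[on_idx][active],
                   method = "spearman")
  list(t = res$t, activities = acts, thetas = thetas, off = off,
       on_idx = on_idx, peak_times = peak_times, active = active,
       spearman = sp, pop = pop, ideal = ideal)
}

# Fraction of on-neurons with unimodal (single-bump) activity: after light
# smoothing, count upward crossings of the half-max level.
unimodal_fraction <- function(acts, on_idx, active) {
  idx <- on_idx[active]
  uni <- sapply(idx, function(j) {
    a <- stats::filter(acts[, j], rep(1 / 25, 25), sides = 2)
    a[is.na(a)] <- 0
    th <- max(a) / 2
    up <- sum(diff(a > th) == 1)
    up <= 1
  })
  mean(uni)
}
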