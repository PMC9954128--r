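# Shared helpers for the test suite.  All fixtures are generated in code.

# Empirical spiking rate at constant current.
empirical_rate <- function(J, dt, duration, params = lif_params()) {
  st <- lif_state(length(J))
  n <- 0
  for (k in seq_len(round(duration / dt))) {
    r <- lif_spike_step(st, J, dt, params)
    st <- r$state
    n <- n + r$spikes
  }
  n / duration
}

# Truth signal passed through the same synaptic chain as a probed decode:
# feedforward synapses (vector of taus) then the probe filter.
filter_matched <- function(x, taus, dt) {
  y <- matrix(x, ncol = 1)
  for (tau in taus) y <- filter_signal(synaptic_filter("exponential", tau),
                                       y, dt)
  as.numeric(y)
}

# Lag-major stimulus history (most recent first) from a time-major array.
history_from_frames <- function(frames) {
  L <- dim(frames)[1]
  t(sapply(seq_len(L), function(k) as.numeric(frames[L - k + 1, , ])))
}
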