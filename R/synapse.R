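#' Synaptic filter models
#'
#' Post-synaptic current kernels with unit DC gain.  `exponential`:
#' `h(t) = exp(-t/tau)/tau`; `alpha`: `h(t) = t exp(-t/tau)/tau^2`.  Both
#' vanish for t < 0 and integrate to 1, so a constant pre-synaptic rate
#' passes through unchanged in steady state.
#'
#' @param kind "exponential" or "alpha".
#' @param tau time constant (s), > 0.
#' @return object of class `synaptic_filter`.
#' @export
synaptic_filter <- function(kind = c("exponential", "alpha"), tau = 0.005) {
  kind <- match.arg(kind)
  stopifnot(tau > 0)
  structure(list(kind = kind, tau = tau), class = "synaptic_filter")
}

#' Impulse response samples of a synaptic filter
#'
#' @param filt a [synaptic_filter()].
#' @param t nonnegative lag times (s).
#' @return kernel values; zero for negative t.
#' @export
filter_kernel <- function(filt, t) {
  h <- ifelse(t < 0, 0,
              if (filt$kind == "exponential") exp(-t / filt$tau) / filt$tau
              else t * exp(-t / filt$tau) / filt$tau^2)
  h
}

# Initialize per-connection filter state for a signal of width m.
filter_state <- function(filt, m, value = NULL) {
  y <- if (is.null(value)) numeric(m) else as.numeric(value)
  if (filt$kind == "exponential") list(y = y)
  else list(y = y, z = y)             # alpha = two cascaded one-pole stages
}

# Exact one-step recurrence of the filter; x is the input held over the step.
# For the exponential filter y' = y d + x (1 - d), d = exp(-dt/tau) (ZOH of
# the one-pole system); the alpha filter is two such stages in cascade.
filter_step <- function(filt, state, x, dt) {
  d <- exp(-dt / filt$tau)
  if (filt$kind == "exponential") {
    state$y <- state$y * d + x * (1 - d)
  } else {
    state$z <- state$z * d + x * (1 - d)
    state$y <- state$y * d + state$z * (1 - d)
  }
  state
}

# Filter a signal offline: x is a T x m matrix sampled at dt; returns the
# filtered signal, same shape.
filter_signal <- function(filt, x, dt) {
  x <- as.matrix(x)
  st <- filter_state(filt, ncol(x))
  out <- matrix(NA_real_, nrow(x), ncol(x))
  for (k in seq_len(nrow(x))) {
    st <- filter_step(filt, st, x[k, ], dt)
    out[k, ] <- st$y
  }
  out
}
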