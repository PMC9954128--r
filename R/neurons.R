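#' Leaky integrate-and-fire parameters
#'
#' Membrane time constant, refractory period and (fixed) unit firing
#' threshold of the LIF neuron model.  These constants are not tied to a
#' particular brain area; the defaults (20 ms membrane, 2 ms refractory) are
#' the standard values used when synthesizing functional spiking networks.
#'
#' @param tau_rc membrane time constant (s), > 0.
#' @param tau_ref absolute refractory period (s), >= 0.
#' @return object of class `lif_params`.
#' @export
lif_params <- function(tau_rc = 0.02, tau_ref = 0.002) {
  stopifnot(tau_rc > 0, tau_ref >= 0)
  structure(list(type = "lif", tau_rc = tau_rc, tau_ref = tau_ref,
                 v_threshold = 1), class = "lif_params")
}

#' Rate-surrogate neuron models
#'
#' Non-spiking rate nonlinearities usable wherever a `lif_params` model is
#' accepted.  `relu_params` fires at `slope * max(0, J - 1)` Hz; sigmoids
#' saturate at `max_rate`.
#'
#' @param slope rate gain in Hz per unit suprathreshold current.
#' @return neuron model object.
#' @export
relu_params <- function(slope = 100) {
  structure(list(type = "relu", slope = slope, v_threshold = 1),
            class = "rate_params")
}

#' @rdname relu_params
#' @param max_rate saturation rate (Hz).
#' @param gain logistic slope.
#' @export
sigmoid_params <- function(max_rate = 200, gain = 4) {
  structure(list(type = "sigmoid", max_rate = max_rate, gain = gain,
                 v_threshold = 1), class = "rate_params")
}

#' Steady-state LIF firing rate
#'
#' Closed-form rate response of the leaky integrate-and-fire neuron: zero at
#' or below threshold, `1 / (tau_ref + tau_rc * log(1/(1 - 1/J)))` above it
#' (threshold current normalized to 1).  Total, continuous and nondecreasing
#' in `J`, saturating at `1/tau_ref`.
#'
#' @param J input current (threshold units); vectorized.
#' @param params a `lif_params` object (or rate surrogate).
#' @return firing rate(s) in Hz.
#' @export
lif_rate <- function(J, params = lif_params()) {
  if (params$type == "relu") return(params$slope * pmax(0, J - 1))
  if (params$type == "sigmoid")
    return(params$max_rate / (1 + exp(-params$gain * (J - 1))))
  r <- numeric(length(J))
  above <- J > params$v_threshold
  if (any(above)) {
    Ja <- J[above]
    # log1p form is stable for large J
    r[above] <- 1 / (params$tau_ref -
                       params$tau_rc * log1p(-params$v_threshold / Ja))
  }
  dim(r) <- dim(J)
  r
}

# Inverse of lif_rate on its increasing branch: current giving `rate` Hz.
lif_rate_inverse <- function(rate, params = lif_params()) {
  stopifnot(all(rate > 0), all(rate < 1 / max(params$tau_ref, 1e-12)))
  params$v_threshold / (1 - exp((params$tau_ref - 1 / rate) / params$tau_rc))
}

#' Initialize LIF spiking state
#'
#' @param n number of neurons.
#' @return list with membrane voltages and refractory clocks.
#' @export
lif_state <- function(n) {
  list(voltage = numeric(n), refractory = numeric(n))
}

#' One simulation step of the spiking LIF model
#'
#' Exact exponential membrane update with sub-step spike timing: on a
#' threshold crossing the spike time within the step is located analytically
#' and the refractory clock is set from it, so long-run spike counts match
#' the closed-form rate to well under 1% at typical rates.
#'
#' @param state list from [lif_state()].
#' @param J input current per neuron (vector).
#' @param dt step size (s), > 0.
#' @param params `lif_params`.
#' @return list(state = updated state, spikes = 0/1 spike indicator vector).
#' @export
lif_spike_step <- function(state, J, dt, params = lif_params()) {
  stopifnot(dt > 0)
  v <- state$voltage
  ref <- pmax(state$refractory - dt, -dt)
  delta_t <- pmin(pmax(dt - ref, 0), dt)
  v <- J + (v - J) * exp(-delta_t / params$tau_rc)
  spiked <- v > params$v_threshold
  spikes <- as.numeric(spiked)
  if (any(spiked)) {
    # time left in the step after the crossing
    t_spike <- dt + params$tau_rc *
      log1p(-(v[spiked] - params$v_threshold) /
              (J[spiked] - params$v_threshold))
    v[spiked] <- 0
    ref[spiked] <- params$tau_ref + t_spike
  }
  list(state = list(voltage = v, refractory = ref), spikes = spikes)
}

#' Solve for gain and bias from maximum rate and intercept
#'
#' Inverts the closed-form LIF rate curve so that the tuning curve fires at
#' 0 Hz when the encoded similarity equals `intercept` and at `max_rate`
#' when it equals 1.
#'
#' @param max_rate firing rate at unit similarity (Hz); must be attainable,
#'   i.e. below `1/tau_ref`.
#' @param intercept similarity at rate onset, in `[-1, 1)`.
#' @param params neuron model.
#' @return list(gain, bias); vectorized over `max_rate`/`intercept`.
#' @export
solve_gain_bias <- function(max_rate, intercept, params = lif_params()) {
  stopifnot(all(intercept < 1))
  if (params$type == "lif") {
    stopifnot(all(max_rate > 0), all(max_rate < 1 / params$tau_ref))
    j_max <- lif_rate_inverse(max_rate, params)
  } else if (params$type == "relu") {
    j_max <- 1 + max_rate / params$slope
  } else {
    stop("solve_gain_bias supports lif and relu models")
  }
  gain <- (j_max - params$v_threshold) / (1 - intercept)
  bias <- params$v_threshold - gain * intercept
  list(gain = gain, bias = bias)
}
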