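#' Ideal SSP path integration
#'
#' Integrates the Fourier-domain oscillator dynamics exactly: each frequency
#' component's phase advances by `a_j . v(t) dt` per step, so the phasors
#' stay exactly unitary and a constant velocity reproduces
#' `phi(x0 + v T)` to machine precision.
#'
#' @param space an [ssp_space()].
#' @param x0 initial position (m-vector).
#' @param velocity T x m matrix of velocities sampled at `dt`.
#' @param dt step (s).
#' @param return_ssp if TRUE (default) return the T x d SSP trajectory;
#'   otherwise the T x d phase trajectory.
#' @return matrix of SSPs (or phases), one row per step (state after the
#'   step).
#' @export
path_integrate_ideal <- function(space, x0, velocity, dt,
                                 return_ssp = TRUE) {
  velocity <- matrix(velocity, ncol = space$m)
  phases <- as.numeric(space$A %*% x0)
  increments <- velocity %*% t(space$A) * dt        # T x d
  ph <- sweep(apply(increments, 2, cumsum), 2, phases, `+`)
  if (!return_ssp) return(ph)
  t(Re(stats::mvfft(t(exp(1i * ph)), inverse = TRUE)) / space$d)
}

# Assemble a full conjugate-symmetric Fourier coefficient vector from free
# component values (complex, length n_free) and take the IDFT.
ssp_from_free <- function(space, zfree) {
  F <- complex(space$d)
  F[1] <- 1
  F[space$free] <- zfree
  F[space$d + 2 - space$free] <- Conj(zfree)
  idft_real(F)
}

#' Spiking path integrator
#'
#' One recurrently connected population per conjugate frequency pair
#' represents the triple (Re, Im, projected velocity); recurrent weights are
#' solved for the low-pass-compensated velocity-controlled-oscillator update
#' (a nonlinear product of the represented frequency with the phasor), and
#' the velocity channel is driven externally.  All oscillator populations
#' share tuning and decoders (solved once), and the simulation is vectorized
#' across oscillators.  The decoded SSP is assembled from the oscillator
#' pairs and decoded to a position with [ssp_decode()] at `decode_every`
#' intervals.
#'
#' @param space an [ssp_space()].
#' @param x0 initial position.
#' @param velocity T x m velocity matrix sampled at `dt`.
#' @param dt simulation step (s).
#' @param n_per_osc neurons per oscillator population.
#' @param tau recurrent synapse time constant (s).
#' @param tau_in input synapse time constant (s).
#' @param kappa radial stabilization rate (1/s): the recurrent function
#'   includes a limit-cycle term pulling each phasor back to unit magnitude,
#'   without which spiking noise makes the neutrally stable radius drift
#'   over long runs.
#' @param decode_every decode interval (s).
#' @param lower,upper decode search box (defaults to a box spanning the
#'   integrated path, padded).
#' @param seed seed for population sampling.
#' @return list: `t_dec`, `path` (decoded positions), `ssp` (decoded SSPs at
#'   decode times), `reliable` flags, and `z` final oscillator states.
#' @export
path_integrate_neural <- function(space, x0, velocity, dt = 1e-3,
                                  n_per_osc = 500, tau = 0.1, tau_in = 0.005,
                                  kappa = 5, decode_every = 0.1,
                                  lower = NULL, upper = NULL, seed = 1) {
  velocity <- matrix(velocity, ncol = space$m)
  Tn <- nrow(velocity)
  Afree <- space$A[space$free, , drop = FALSE]      # n_osc x m
  n_osc <- nrow(Afree)
  omega <- velocity %*% t(Afree)                    # T x n_osc true a_j.v
  omega_scale <- max(abs(omega)) * 1.1 + 1e-9
  w_norm <- omega / omega_scale
  # shared 3-d population: z = (Re, Im, w)
  set.seed(seed)
  pop <- population(n_per_osc, 3, max_rates = c(200, 400),
                    intercepts = c(-0.95, 0.95), radius = 1.45)
  cc <- tau * omega_scale
  g <- function(z) {
    r <- sqrt(z[1]^2 + z[2]^2)
    lc <- tau * kappa * (1 - r)                     # unit-circle attractor
    c(z[1] - cc * z[3] * z[2] + lc * z[1],
      z[2] + cc * z[3] * z[1] + lc * z[2])
  }
  # train the recurrent decoders on the operating manifold (phasors near
  # the unit circle at all represented frequencies), with light
  # regularization: any tangential decode bias acts as a frequency offset
  # that integrates into unbounded phase drift, so after the first solve the
  # residual phase-rate bias is measured around the ring (rate model) and
  # cancelled by a counter-rotation in the target
  N_train <- 4000
  th <- stats::runif(N_train, 0, 2 * pi)
  rr <- stats::runif(N_train, 0.8, 1.2)
  sig <- cbind(rr * cos(th), rr * sin(th),
               stats::runif(N_train, -1, 1))
  reg <- 0.02
  Dg <- solve_decoders(pop, g, signals = sig, reg = reg)
  wg <- seq(-0.95, 0.95, length.out = 9)
  thg <- seq(0, 2 * pi, length.out = 49)[-49]
  bias_w <- sapply(wg, function(w) {
    mean(sapply(thg, function(t0) {
      z <- c(cos(t0), sin(t0), w)
      gh <- as.numeric(Dg %*% static_tuning(pop, z))
      sum((gh - g(z)) * c(-sin(t0), cos(t0))) / tau
    }))
  })
  corr <- stats::approxfun(wg, bias_w, rule = 2)
  g_cal <- function(z) {
    r <- sqrt(z[1]^2 + z[2]^2) + 1e-12
    g(z) - tau * corr(z[3]) * c(-z[2], z[1]) / r
  }
  Dg <- solve_decoders(pop, g_cal, signals = sig, reg = reg)
  # initial phasor per oscillator
  ph0 <- as.numeric(Afree %*% x0)
  z12 <- rbind(Re(exp(1i * ph0)), Im(exp(1i * ph0)))  # 2 x n_osc
  # filter states: recurrent (2 x n_osc) initialized at g(z0), input (n_osc)
  rec_y <- z12                                      # g(z0) with w = 0
  in_y <- numeric(n_osc)
  d_rec <- exp(-dt / tau); d_in <- exp(-dt / tau_in)
  vstate <- list(voltage = matrix(0, n_per_osc, n_osc),
                 refractory = matrix(0, n_per_osc, n_osc))
  E <- pop$encoders                                 # n x 3
  n_dec <- max(1L, round(decode_every / dt))
  if (is.null(lower) || is.null(upper)) {
    px <- apply(rbind(x0, x0 + apply(velocity * dt, 2, cumsum)), 2, range)
    lower <- px[1, ] - 4 * space$length_scale
    upper <- px[2, ] + 4 * space$length_scale
  }
  t_dec <- c(); path <- NULL; rel <- c(); ssps <- NULL
  spikes <- matrix(0, n_per_osc, n_osc)
  for (k in seq_len(Tn)) {
    # input synapse on the velocity channel
    in_y <- in_y * d_in + w_norm[k, ] * (1 - d_in)
    # currents: encoders applied to (rec_y; in_y) per oscillator
    X <- rbind(rec_y, in_y) / pop$radius            # 3 x n_osc
    J <- (E %*% X) * pop$gains + pop$biases
    st <- lif_spike_step(list(voltage = vstate$voltage,
                              refractory = vstate$refractory),
                         J, dt, pop$neuron)
    vstate <- st$state
    spikes <- st$spikes / dt
    dim(spikes) <- c(n_per_osc, n_osc)
    dec <- Dg %*% spikes                            # 2 x n_osc decoded g(z)
    rec_y <- rec_y * d_rec + dec * (1 - d_rec)
    if (k %% n_dec == 0) {
      zf <- complex(real = rec_y[1, ], imaginary = rec_y[2, ])
      v_ssp <- ssp_from_free(space, zf)
      est <- ssp_decode(space, v_ssp, lower = lower, upper = upper,
                        resolution = 41)
      t_dec <- c(t_dec, k * dt)
      path <- rbind(path, est$x)
      rel <- c(rel, est$reliable)
      ssps <- rbind(ssps, v_ssp)
    }
  }
  list(t_dec = t_dec, path = path, reliable = rel, ssp = ssps,
       z = rec_y, omega_scale = omega_scale)
}

#' Joint space-time SSP encoding
#'
#' `phi(x, t) = IDFT[exp(i (A x + b t))]`, i.e. the spatial SSP bound with a
#' temporal SSP; at t = 0 it reduces to the spatial encoding.
#'
#' @param space an [ssp_space()].
#' @param b d-vector of time-phase slopes (see [time_phase_vector()]).
#' @param x position (m-vector).
#' @param t elapsed-time coordinate (s).
#' @return d-vector.
#' @export
encode_spacetime <- function(space, b, x, t) {
  idft_real(exp(1i * (as.numeric(space$A %*% x) + b * t)))
}

#' Time-phase encoding vector
#'
#' Conjugate-symmetric phase-slope vector for the time axis, built exactly
#' like a 1-D SSP space with its own length scale (the temporal resolution of
#' the trajectory memory).
#'
#' @param d dimensionality (odd, matching the spatial space).
#' @param length_scale_t seconds per unit phase scale.
#' @param seed optional seed.
#' @return d-vector `b` with `b[1] = 0` and conjugate symmetry.
#' @export
time_phase_vector <- function(d, length_scale_t = 1, seed = NULL) {
  stopifnot(d %% 2 == 1)
  if (!is.null(seed)) set.seed(seed)
  n_free <- (d - 1) / 2
  w <- 2 * pi / (length_scale_t * n_free)
  ph <- -pi / length_scale_t + (seq_len(n_free) - 1) * w +
    stats::runif(n_free) * w
  c(0, ph, -rev(ph))
}

#' Ideal temporal integration of a trajectory memory
#'
#' Steps `Phi' = IDFT{i b} (*) Phi + phi(x(t))` in the Fourier domain: each
#' coefficient rotates at its time-frequency `b_k` (exact per-step rotation)
#' and accumulates the input encoding (Euler, weight `dt`).  With `b = 0`
#' this is a pure running sum of encodings.
#'
#' @param space an [ssp_space()].
#' @param b time-phase vector (length d).
#' @param x T x m matrix (or vector) of input values sampled at `dt`.
#' @param dt step (s).
#' @param decay optional leak rate (1/s, default 0: no forgetting).
#' @return T x d matrix of memory vectors Phi(t).
#' @export
temporal_integrate <- function(space, b, x, dt, decay = 0) {
  x <- matrix(x, ncol = space$m)
  Tn <- nrow(x)
  rot <- exp((1i * b - decay) * dt)
  Fin <- exp(1i * (space$A %*% t(x)))               # d x T input spectra
  Phi <- complex(space$d)
  out <- matrix(NA_real_, Tn, space$d)
  for (k in seq_len(Tn)) {
    Phi <- Phi * rot + Fin[, k] * dt
    out[k, ] <- idft_real(Phi)
  }
  out
}

#' Similarity surface of a trajectory memory
#'
#' Dot products of a memory vector with space-time encodings over a grid of
#' values and lags; ridges mark where the trajectory was at each time in the
#' past.
#'
#' @param space an [ssp_space()] (m = 1).
#' @param b time-phase vector.
#' @param Phi memory d-vector.
#' @param values numeric grid of x values.
#' @param lags numeric grid of elapsed times (s).
#' @return matrix length(values) x length(lags) of similarities.
#' @export
trajectory_similarity_map <- function(space, b, Phi, values, lags) {
  out <- matrix(NA_real_, length(values), length(lags))
  FPhi <- Conj(stats::fft(Phi))
  for (j in seq_along(lags)) {
    ph <- exp(1i * (space$A %*% t(matrix(values, ncol = space$m)) +
                      b * lags[j]))
    out[, j] <- Re(crossprod(ph, FPhi)) / space$d
  }
  out
}

#' Spiking temporal integrator
#'
#' Realizes the trajectory-memory dynamics in recurrent spiking populations:
#' one 2-d population per conjugate frequency pair (plus one for the real
#' zero-frequency accumulator), each implementing its 2 x 2 rotation block
#' mapped through the recurrent low-pass (`A' = tau A + I`, `B' = tau I`).
#' The input encoding `phi(x(t))` enters through the input synapse scaled by
#' `tau`.  States are represented scaled by `radius` (the expected memory
#' magnitude over the design window).
#'
#' @param space an [ssp_space()].
#' @param b time-phase vector.
#' @param x input values (T x m) sampled at `dt`.
#' @param dt simulation step (s).
#' @param n_per_pair neurons per frequency-pair population.
#' @param tau recurrent synapse (s).
#' @param max_rates sampled firing-rate range (Hz); high rates keep the
#'   resonant spike-noise accumulation small.
#' @param radius_margin headroom factor on the per-pair representation radii
#'   (each pair's radius is this factor times the peak ideal coefficient
#'   magnitude, so slowly rotating components get the range they need).
#' @param seed population sampling seed.
#' @return list: `Phi` (T x d decoded memory trajectory), `ideal` (T x d
#'   ideal trajectory).
#' @export
neural_temporal_integrator <- function(space, b, x, dt = 1e-3,
                                       n_per_pair = 200, tau = 0.2,
                                       max_rates = c(200, 400),
                                       radius_margin = 1.25, seed = 1) {
  x <- matrix(x, ncol = space$m)
  Tn <- nrow(x)
  n_free <- length(space$free)
  bf <- b[space$free]
  # per-pair representation radii from the ideal coefficient envelope
  ideal <- temporal_integrate(space, b, x, dt)
  Fid <- stats::mvfft(t(ideal))                     # d x T coefficients
  rk <- radius_margin * apply(Mod(Fid[space$free, , drop = FALSE]), 1, max)
  rk <- pmax(rk, 1e-3)
  r0 <- radius_margin * max(Mod(Fid[1, ])) + 1e-3
  set.seed(seed)
  # shared 2-d population for all pairs; a 1-d population for the DC term
  pop <- population(n_per_pair, 2, max_rates = max_rates,
                    intercepts = c(-0.95, 0.95), radius = 1.05)
  Did <- solve_decoders(pop, NULL, N = 1500)        # identity decoders 2 x n
  pop0 <- population(n_per_pair, 1, max_rates = max_rates,
                     intercepts = c(-0.95, 0.95), radius = 1.05)
  Did0 <- solve_decoders(pop0, NULL, N = 1000)
  # recurrent transforms per pair: tau*[[0,-b],[b,0]] + I
  rot_c <- 1 + 0 * bf; rot_s <- tau * bf
  Fin <- exp(1i * (space$A[space$free, , drop = FALSE] %*% t(x)))  # free x T
  d_rec <- exp(-dt / tau)
  # states
  rec_y <- matrix(0, 2, n_free)                     # filtered recurrent
  in_y <- matrix(0, 2, n_free)                      # filtered input
  rec0 <- 0; in0 <- 0
  vs <- list(voltage = matrix(0, n_per_pair, n_free),
             refractory = matrix(0, n_per_pair, n_free))
  vs0 <- lif_state(n_per_pair)
  E <- pop$encoders
  out <- matrix(NA_real_, Tn, space$d)
  for (k in seq_len(Tn)) {
    u <- Fin[, k]
    in_y <- in_y * d_rec + rbind(Re(u), Im(u)) * (tau * (1 - d_rec))
    in0 <- in0 * d_rec + 1 * (tau * (1 - d_rec))    # DC input coeff is 1
    X <- sweep(rec_y + in_y, 2, pop$radius * rk, `/`)
    J <- (E %*% X) * pop$gains + pop$biases
    st <- lif_spike_step(vs, J, dt, pop$neuron)
    vs <- st$state
    spikes <- st$spikes / dt
    dim(spikes) <- c(n_per_pair, n_free)
    z <- sweep(Did %*% spikes, 2, rk, `*`)          # 2 x n_free decoded
    # apply per-pair rotation transform (tau A + I)
    zr <- rbind(rot_c * z[1, ] - rot_s * z[2, ],
                rot_s * z[1, ] + rot_c * z[2, ])
    rec_y <- rec_y * d_rec + zr * (1 - d_rec)
    # DC accumulator population
    J0 <- pop0$gains * (pop0$encoders[, 1] * ((rec0 + in0) /
                                                (pop0$radius * r0))) +
      pop0$biases
    s0 <- lif_spike_step(vs0, J0, dt, pop0$neuron)
    vs0 <- s0$state
    z0 <- sum(Did0 * (s0$spikes / dt)) * r0
    rec0 <- rec0 * d_rec + z0 * (1 - d_rec)
    # read the memory out through the synaptic filter (the represented
    # state), not from raw single-step spike decodes
    zrep <- rec_y + in_y
    out[k, ] <- ssp_from_free2(space, complex(real = zrep[1, ],
                                              imaginary = zrep[2, ]),
                               rec0 + in0)
  }
  list(Phi = out, ideal = ideal)
}

# Fourier assembly with an explicit DC coefficient.
ssp_from_free2 <- function(space, zfree, dc) {
  F <- complex(space$d)
  F[1] <- dc
  F[space$free] <- zfree
  F[space$d + 2 - space$free] <- Conj(zfree)
  idft_real(F)
}
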