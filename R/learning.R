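#' Prescribed Error Sensitivity (PES) decoder update
#'
#' Delta-style online rule on decoders read out of a population:
#' `Delta d_i = -(lambda * dt / n) * epsilon * a_i`, where `a_i` is the
#' (filtered) activity of neuron i in Hz and `epsilon` the error in the
#' decoded space.  The `1/n` scaling makes learning rates roughly
#' population-size invariant.
#'
#' @param decoders dim_out x n decoder matrix being learned.
#' @param activities length-n activity vector (Hz).
#' @param error dim_out error vector (decoded estimate minus target).
#' @param learning_rate lambda (1/(Hz * s), after the 1/n scaling).
#' @param dt step (s).
#' @return updated decoder matrix.
#' @export
pes_update <- function(decoders, activities, error, learning_rate, dt) {
  decoders - (learning_rate * dt / length(activities)) *
    (as.matrix(error) %*% t(as.matrix(activities)))
}

#' Online pendulum-angle prediction with PES learning
#'
#' Reproduces the torque-plus-delayed-angle prediction task: a recurrent
#' spiking population carries time-cell tuning over both input channels (two
#' Legendre Delay Network systems realized in one population through the
#' low-pass-compensated recurrent transform), and PES learns — from zero
#' initial decoders — to reconstruct the *current* pendulum angle from the
#' delayed sensory channel and the torque history.  The error signal is the
#' difference between the prediction and the actual angle.
#'
#' @param duration simulated time (s).
#' @param dt step (s).
#' @param n_neurons population size.
#' @param q LDN order per channel.
#' @param theta LDN window (s).
#' @param tau_rec recurrent synapse (s).
#' @param tau_learn synapse filtering activities and prediction for learning
#'   and readout (s).
#' @param learning_rate PES rate; the default is a moderate rate at which the
#'   error converges well within the default 200 s run.  Larger stable rates
#'   exist ([tune_learning_rate()] finds them) and converge somewhat lower;
#'   all rates in the stable range land near the same asymptote.
#' @param sensory_delay delay of the angle channel (s).
#' @param pendulum list of physics overrides passed to [gen_pendulum()].
#' @param seed integer seed (pendulum, tuning sampling).
#' @return list: `t`, `angle`, `prediction`, `nrmse_final` (final-quarter
#'   normalized RMSE), `nrmse_trace` (per-10 s windows), `config`.
#' @export
run_pendulum_prediction <- function(duration = 200, dt = 1e-3,
                                    n_neurons = 400, q = 7, theta = 0.5,
                                    tau_rec = 0.1, tau_learn = 0.02,
                                    learning_rate = 2e-3,
                                    sensory_delay = 0.05,
                                    pendulum = list(), seed = 1) {
  set.seed(seed)
  pend <- do.call(gen_pendulum,
                  c(list(duration = duration, dt = dt,
                         sensory_delay = sensory_delay), pendulum))
  n_steps <- nrow(pend)
  # normalize the two input channels to comparable unit scale
  s_tq <- 2.5 * sqrt(mean(pend$torque^2))
  s_ang <- 2.5 * sqrt(mean(pend$angle^2))
  U <- cbind(pend$torque / s_tq, pend$angle_delayed / s_ang)
  # dual-LDN state space (one LDN per channel in a single population)
  ldn <- make_ldn(q, theta)
  A2 <- as.matrix(Matrix::bdiag(ldn$A, ldn$A))
  B2 <- as.matrix(Matrix::bdiag(ldn$B, ldn$B))
  sys2 <- lti_system(A2, B2, theta, "custom")
  tr <- map_lti_through_lowpass(sys2, tau_rec)
  # representation radius from the ideal state trajectory (first 20 s)
  pilot <- lti_simulate(sys2, U[seq_len(min(n_steps, 20 / dt)), ], dt)
  radius <- 1.2 * max(sqrt(rowSums(pilot^2)))
  pop <- population(n_neurons, 2 * q, max_rates = c(100, 200),
                    intercepts = c(-1, 1), radius = radius)
  Dx <- solve_decoders(pop, NULL, N = 3000)        # identity state decoders
  E <- pop$encoders
  d_rec <- exp(-dt / tau_rec); d_l <- exp(-dt / tau_learn)
  rec_y <- numeric(2 * q); in_y <- numeric(2 * q)
  act_f <- numeric(n_neurons)                      # filtered activities
  D <- matrix(0, 1, n_neurons)                     # learned decoders (zero)
  vs <- lif_state(n_neurons)
  pred <- numeric(n_steps)
  yhat_f <- 0
  for (k in seq_len(n_steps)) {
    in_y <- in_y * d_rec + as.numeric(tr$Bp %*% U[k, ]) * (1 - d_rec)
    x_rep <- rec_y + in_y
    J <- pop$gains * as.numeric(E %*% (x_rep / radius)) + pop$biases
    st <- lif_spike_step(vs, J, dt, pop$neuron)
    vs <- st$state
    spikes <- st$spikes / dt
    rec_y <- rec_y * d_rec +
      as.numeric(tr$Ap %*% (Dx %*% spikes)) * (1 - d_rec)
    act_f <- act_f * d_l + spikes * (1 - d_l)
    yhat_f <- yhat_f * d_l + as.numeric(D %*% spikes) * (1 - d_l)
    pred[k] <- yhat_f * s_ang
    err <- (pred[k] - pend$angle[k]) / s_ang
    D <- pes_update(D, act_f, err, learning_rate, dt)
  }
  final <- seq.int(floor(3 * n_steps / 4) + 1L, n_steps)
  nr_final <- nrmse(pred[final], pend$angle[final])
  win <- max(1L, round(10 / dt))
  nwin <- floor(n_steps / win)
  nr_trace <- sapply(seq_len(nwin), function(w) {
    i <- ((w - 1) * win + 1):(w * win)
    nrmse(pred[i], pend$angle[i])
  })
  list(t = pend$t, angle = pend$angle, prediction = pred,
       nrmse_final = nr_final, nrmse_trace = nr_trace,
       diverged = any(nr_trace[-1] > 1.5),
       config = list(duration = duration, dt = dt, n_neurons = n_neurons,
                     q = q, theta = theta, learning_rate = learning_rate,
                     sensory_delay = sensory_delay, seed = seed))
}

#' Doubling search for the largest stable learning rate
#'
#' Runs a task at geometrically increasing learning rates and returns the
#' largest rate whose error trace stays bounded (no sustained normalized
#' error above the stability threshold) and whose final error improves on
#' the next-smaller rate's.
#'
#' @param run_fn function(learning_rate) returning a list with
#'   `nrmse_trace` and `nrmse_final`.
#' @param rate0 starting rate.
#' @param max_doublings maximum number of doublings.
#' @param threshold sustained-error stability bound.
#' @return the selected learning rate.
#' @export
tune_learning_rate <- function(run_fn, rate0 = 1e-4, max_doublings = 8,
                               threshold = 1.2) {
  best <- NA_real_
  best_err <- Inf
  rate <- rate0
  for (i in seq_len(max_doublings)) {
    res <- run_fn(rate)
    tr <- res$nrmse_trace
    stable <- !any(tr[-1] > threshold) && is.finite(res$nrmse_final)
    if (stable && res$nrmse_final < best_err) {
      best <- rate
      best_err <- res$nrmse_final
    }
    if (!stable) break
    rate <- rate * 2
  }
  if (is.na(best)) stop("no stable learning rate found from rate0")
  best
}

#' Learned Legendre Predictor state
#'
#' Online multi-step prediction: a coefficient matrix `M` (n x q x dim_out)
#' maps current activities to shifted-Legendre coefficients of the predicted
#' observation over the future window `[t, t + theta]`.  Two LDN memories
#' support learning once ground truth arrives: one stores each neuron's
#' recent activity, the other the recent prediction coefficients, so the
#' update needs only Legendre-basis evaluations of stored quantities.
#'
#' @param n number of neurons feeding the predictor.
#' @param q prediction basis order.
#' @param q_a memory (LDN) order for stored activities/predictions.
#' @param theta prediction horizon = memory window (s).
#' @param dim_out observation dimensionality.
#' @param learning_rate update rate.
#' @param n_lags quadrature lags for credit assignment across the window.
#' @param relative if TRUE, predict the *displacement* of the observation
#'   over the window rather than its absolute value (a third LDN memory
#'   stores recent observations so learning can reconstruct absolute
#'   targets); linear motion then extrapolates exactly.
#' @return object of class `llp_state`.
#' @export
llp_init <- function(n, q = 10, q_a = 10, theta = 0.5, dim_out = 1,
                     learning_rate = 2, n_lags = 8, relative = FALSE) {
  mem <- make_ldn(q_a, theta)
  lag_fracs <- (seq_len(n_lags) - 0.5) / n_lags
  structure(list(
    M = array(0, c(n, q, dim_out)),
    mem = mem, theta = theta, q = q, q_a = q_a, n = n, dim_out = dim_out,
    learning_rate = learning_rate, relative = relative,
    lag_fracs = lag_fracs,
    # readout matrices: decode memory state at each lag
    lag_readout = shifted_legendre(q_a, lag_fracs),      # n_lags x q_a
    # Legendre basis of the prediction evaluated at lead = lag (the
    # prediction made at t - s for lead s targets time t)
    pred_basis = shifted_legendre(q, lag_fracs),         # n_lags x q
    act_mem = matrix(0, q_a, n),                         # activity LDN
    coef_mem = array(0, c(q_a, q, dim_out)),             # prediction LDN
    obs_mem = matrix(0, q_a, dim_out),                   # observation LDN
    z_now = numeric(dim_out),
    disc = NULL), class = "llp_state")
}

#' One LLP step: predict, store, learn
#'
#' Reads out the predicted future window from current activities, pushes
#' activities and prediction coefficients into their LDN memories, and — now
#' that the observation `z` for the present moment is available — applies the
#' delta-style update against what was predicted for *now* across the stored
#' past, with credit assigned to the stored activities.
#'
#' @param state an [llp_init()] object.
#' @param activities length-n activity vector (Hz, filtered).
#' @param z current observation (length dim_out).
#' @param dt step (s).
#' @return updated state; element `coef` holds the current prediction
#'   coefficients (q x dim_out).
#' @export
llp_update <- function(state, activities, z, dt) {
  if (is.null(state$disc)) state$disc <- discretize_lti(state$mem, dt)
  a <- as.numeric(activities)
  # current prediction coefficients (q x dim_out)
  coef <- apply(state$M, 3, function(Mk) crossprod(Mk, a))
  coef <- matrix(coef, state$q, state$dim_out)
  # learning: compare z against stored predictions for the present
  RL <- state$lag_readout                      # n_lags x q_a
  a_past <- RL %*% state$act_mem               # n_lags x n stored activities
  # normalized-LMS scaling: the step corrects a fixed fraction of the error
  # per unit time regardless of activity magnitude
  denom <- rowSums(a_past^2) + state$n   # floor guards the empty memory
  lr <- state$learning_rate * dt / length(state$lag_fracs)
  z_past <- RL %*% state$obs_mem               # n_lags x dim_out stored z
  for (m in seq_len(state$dim_out)) {
    cpast <- RL %*% state$coef_mem[, , m]      # n_lags x q stored coefs
    pred_now <- rowSums(cpast * state$pred_basis)        # predicted z_m(t)
    if (state$relative) pred_now <- pred_now + z_past[, m]
    e <- pred_now - z[m]                       # error per stored lag
    # gradient step through the Legendre evaluations, local to synapses
    state$M[, , m] <- state$M[, , m] -
      lr * crossprod(a_past / denom, e * state$pred_basis)
  }
  # push current activity, coefficients and observation into the memories
  state$act_mem <- state$disc$Ad %*% state$act_mem +
    state$disc$Bd %*% t(a)
  for (m in seq_len(state$dim_out)) {
    state$coef_mem[, , m] <- state$disc$Ad %*% state$coef_mem[, , m] +
      state$disc$Bd %*% t(coef[, m])
  }
  state$obs_mem <- state$disc$Ad %*% state$obs_mem + state$disc$Bd %*% t(z)
  state$z_now <- z
  state$coef <- coef
  state
}

#' Evaluate an LLP prediction at a future lead time
#'
#' @param state an LLP state with current coefficients (after
#'   [llp_update()]).
#' @param lead lead time(s) in `[0, theta]`.
#' @return length(lead) x dim_out matrix of predicted observations.
#' @export
llp_predict <- function(state, lead) {
  P <- shifted_legendre(state$q, lead / state$theta)
  out <- P %*% matrix(state$coef, state$q, state$dim_out)
  if (state$relative) out <- sweep(out, 2, state$z_now, `+`)
  out
}

#' Bouncing-ball prediction with the LLP
#'
#' The end-to-end multi-step prediction task: a rate-neuron population
#' encodes a context representation of the recent ball motion, and the LLP
#' learns online to predict the ball position over the next `theta` seconds.
#' Contexts: "ldn" (LDN memories of x and y), "ssp" (SSP of current
#' position), "ssp_speed" (SSP of position and velocity).
#'
#' @param context one of "ldn", "ssp", "ssp_speed".
#' @param duration trial length (s).
#' @param dt step (s).
#' @param theta prediction horizon (s).
#' @param q prediction basis order.
#' @param n_neurons context population size.
#' @param learning_rate LLP rate; defaults per context were fixed by the
#'   doubling search.
#' @param box box size for the ball fixture; `walls = FALSE` gives the
#'   straight-line control (box grown so no bounce occurs).
#' @param walls include wall bounces.
#' @param seed integer seed.
#' @return list: `t_eval`, `rmse_windowed` (1 s windows of the realized
#'   error of the `theta`-ahead prediction), `rmse_first`, `rmse_last`,
#'   plus the trajectory and per-step realized errors.
#' @export
run_ball_prediction <- function(context = c("ldn", "ssp", "ssp_speed"),
                                duration = 60, dt = 5e-3, theta = 0.5,
                                q = 10, n_neurons = 250,
                                learning_rate = NULL, box = c(2, 2),
                                walls = TRUE, seed = 1) {
  context <- match.arg(context)
  set.seed(seed)
  ball <- if (walls) {
    gen_bouncing_ball(box = box, duration = duration, dt = dt)
  } else {
    # straight-line control: slow diagonal crossing, no bounce in the trial
    gen_bouncing_ball(box = box, x0 = box * 0.05,
                      v0 = box * 0.88 / duration, duration = duration,
                      dt = dt)
  }
  n_steps <- nrow(ball)
  Z <- cbind(ball$x, ball$y)
  V <- cbind(ball$vx, ball$vy)
  centre <- box / 2
  if (is.null(learning_rate))
    learning_rate <- c(ldn = 2, ssp = 2, ssp_speed = 2)[[context]]
  # context encoding input per step
  if (context == "ldn") {
    ldn <- make_ldn(6, theta)
    A2 <- as.matrix(Matrix::bdiag(ldn$A, ldn$A))
    B2 <- as.matrix(Matrix::bdiag(ldn$B, ldn$B))
    sys2 <- lti_system(A2, B2, theta)
    ctx <- lti_simulate(sys2, sweep(Z, 2, centre) / max(box), dt)
    ctx <- ctx / max(1, max(abs(ctx)))
    pop <- population(n_neurons, ncol(ctx), max_rates = c(100, 200),
                      intercepts = c(-0.9, 0.9), radius = 1.2)
  } else {
    ls <- max(box) / 6
    spc <- ssp_space(d = 2 * floor((n_neurons / 8) / 2) * 2 + 1,
                     m = if (context == "ssp") 2 else 4,
                     kind = "random", length_scale = 1)
    pts <- if (context == "ssp") sweep(Z, 2, centre) / ls else
      cbind(sweep(Z, 2, centre) / ls, V / (2 * ls))
    ctx <- ssp_encode_many(spc, pts)
    pop <- population(n_neurons, ncol(ctx), max_rates = c(100, 200),
                      intercepts = c(0.1, 0.5), radius = 1)
  }
  acts <- t(static_tuning(pop, ctx))           # T x n rate activities
  st <- llp_init(n_neurons, q = q, theta = theta, dim_out = 2,
                 learning_rate = learning_rate, relative = TRUE)
  lead_steps <- round(theta / dt)
  realized_pred <- matrix(NA_real_, n_steps, 2)  # prediction made for t
  for (k in seq_len(n_steps)) {
    st <- llp_update(st, acts[k, ], Z[k, ], dt)
    tgt <- k + lead_steps
    if (tgt <= n_steps) realized_pred[tgt, ] <- llp_predict(st, theta)
  }
  err <- sqrt(rowSums((realized_pred - Z)^2))
  win <- round(1 / dt)
  ok <- which(!is.na(err))
  nwin <- floor(length(ok) / win)
  rmse_w <- sapply(seq_len(nwin), function(w)
    sqrt(mean(err[ok[((w - 1) * win + 1):(w * win)]]^2)))
  list(t_eval = ball$t[ok[seq_len(nwin * win)]],
       rmse_windowed = rmse_w,
       rmse_first = mean(rmse_w[seq_len(min(2, nwin))]),
       rmse_last = mean(rmse_w[seq.int(max(1, nwin - 4), nwin)]),
       error = err, trajectory = ball, context = context,
       learning_rate = learning_rate)
}
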