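#' Synthetic single-joint pendulum run
#'
#' Integrates a damped point-mass pendulum driven by a torque signal with a
#' fourth-order Runge-Kutta scheme and returns torque, angle and a
#' sensory-delayed angle channel.  The default torque is band-limited white
#' noise scaled to swing the arm over roughly a radian.
#'
#' @param duration run length (s).
#' @param dt step (s).
#' @param mass,length_arm,gravity,damping pendulum physics (SI units).  The
#'   default viscous damping (1 N m s) keeps the joint swinging over roughly
#'   plus/minus 2 rad under the default torque drive — well into the
#'   nonlinear range — without winding over the top.
#' @param torque optional torque vector (length `duration/dt`); default
#'   band-limited noise (`torque_bandwidth` Hz, `torque_rms` N m).
#' @param torque_bandwidth,torque_rms torque generation parameters.
#' @param sensory_delay delay of the proprioceptive angle channel (s).
#' @param seed optional seed.
#' @return data frame (t, torque, angle, velocity, angle_delayed).
#' @export
gen_pendulum <- function(duration = 200, dt = 1e-3, mass = 1,
                         length_arm = 1, gravity = 9.81, damping = 1,
                         torque = NULL, torque_bandwidth = 1,
                         torque_rms = 3, sensory_delay = 0.05,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration / dt)
  if (is.null(torque))
    torque <- bandlimited_noise(duration, dt, torque_bandwidth, torque_rms)
  stopifnot(length(torque) == n)
  I <- mass * length_arm^2
  deriv <- function(state, tq) {
    c(state[2],
      (tq - damping * state[2] -
         mass * gravity * length_arm * sin(state[1])) / I)
  }
  out <- matrix(NA_real_, n, 2)
  s <- c(0, 0)
  for (k in seq_len(n)) {
    tq <- torque[k]                       # ZOH torque over the step
    k1 <- deriv(s, tq)
    k2 <- deriv(s + dt / 2 * k1, tq)
    k3 <- deriv(s + dt / 2 * k2, tq)
    k4 <- deriv(s + dt * k3, tq)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[k, ] <- s
  }
  lag <- round(sensory_delay / dt)
  delayed <- c(rep(0, lag), out[seq_len(n - lag), 1])
  data.frame(t = seq_len(n) * dt, torque = torque, angle = out[, 1],
             velocity = out[, 2], angle_delayed = delayed)
}

#' Bouncing-ball trajectory
#'
#' Straight-line motion in a rectangular box with exact specular, lossless
#' reflections (speed conserved to machine precision).
#'
#' @param box c(width, height).
#' @param x0,v0 initial position and velocity.  The default velocity ratio is
#'   rational (3:2), so the orbit closes after 20 s and revisits the same
#'   positions with the same headings — the regime in which position-based
#'   context encodings can learn to predict the motion.
#' @param duration,dt run length and sampling step (s).
#' @return data frame (t, x, y, vx, vy).
#' @export
gen_bouncing_ball <- function(box = c(2, 2), x0 = c(0.5, 0.7),
                              v0 = c(0.6, 0.4), duration = 60, dt = 5e-3) {
  n <- round(duration / dt)
  pos <- x0; vel <- v0
  out <- matrix(NA_real_, n, 4)
  for (k in seq_len(n)) {
    remaining <- dt
    while (remaining > 0) {
      # time to each wall along current velocity
      t_hit <- remaining
      wall <- 0L
      for (j in 1:2) {
        if (vel[j] > 0) th <- (box[j] - pos[j]) / vel[j]
        else if (vel[j] < 0) th <- -pos[j] / vel[j]
        else next
        if (th < t_hit) { t_hit <- th; wall <- j }
      }
      pos <- pos + vel * t_hit
      remaining <- remaining - t_hit
      if (wall > 0L) vel[wall] <- -vel[wall]
    }
    out[k, ] <- c(pos, vel)
  }
  data.frame(t = seq_len(n) * dt, x = out[, 1], y = out[, 2],
             vx = out[, 3], vy = out[, 4])
}

#' Smooth random-walk trajectory in an arena
#'
#' Low-pass-filtered white-noise velocity, reflected at the arena boundary;
#' a synthetic stand-in for open-field foraging paths.  Defaults mirror a
#' 60 s session in a 180 cm diameter circular arena.
#'
#' @param arena list(kind = "circle", diameter =) or
#'   list(kind = "rect", width =, height =); units are whatever the caller
#'   uses consistently (cm by default conventions here).
#' @param duration,dt run length and sampling step (s).
#' @param mean_speed target mean speed (units/s).
#' @param smoothness velocity low-pass time constant (s).
#' @param seed optional seed.
#' @return data frame (t, x, y) of class trajectory, centred at the origin.
#' @export
gen_trajectory_2d <- function(arena = list(kind = "circle", diameter = 180),
                              duration = 60, dt = 0.02, mean_speed = 20,
                              smoothness = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration / dt)
  # OU-style smooth velocity
  v <- matrix(0, n, 2)
  a <- exp(-dt / smoothness)
  sd_drive <- sqrt(1 - a^2)
  for (k in 2:n) v[k, ] <- v[k - 1, ] * a + stats::rnorm(2, 0, sd_drive)
  sp <- sqrt(rowSums(v^2))
  v <- v * mean_speed / mean(sp)
  inside <- function(p) {
    if (arena$kind == "circle") sum(p^2) <= (arena$diameter / 2)^2
    else abs(p[1]) <= arena$width / 2 && abs(p[2]) <= arena$height / 2
  }
  p <- c(0, 0)
  out <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    cand <- p + v[k, ] * dt
    if (!inside(cand)) {
      if (arena$kind == "circle") {
        nrm <- cand / sqrt(sum(cand^2))
        v[k, ] <- v[k, ] - 2 * sum(v[k, ] * nrm) * nrm     # reflect
        if (k < n) v[k + 1, ] <- v[k, ]
      } else {
        if (abs(cand[1]) > arena$width / 2) v[k, 1] <- -v[k, 1]
        if (abs(cand[2]) > arena$height / 2) v[k, 2] <- -v[k, 2]
        if (k < n) v[k + 1, ] <- v[k, ]
      }
      cand <- p + v[k, ] * dt
      if (!inside(cand)) cand <- p                          # corner case
    }
    p <- cand
    out[k, ] <- p
  }
  data.frame(t = seq_len(n) * dt, x = out[, 1], y = out[, 2])
}

#' Drifting sinusoidal grating stimulus
#'
#' Unit-amplitude spatiotemporal stimulus on a square pixel grid, moving in
#' a given direction; temporal frequency equals speed times spatial
#' frequency.
#'
#' @param direction motion direction (radians; 0 = rightward, pi/2 = up).
#' @param spatial_freq cycles per unit distance.
#' @param speed drift speed (units/s).
#' @param grid_size pixels per side (unit square).
#' @param duration,dt run length and step (s).
#' @return array (time, pixel_x, pixel_y).
#' @export
gen_grating <- function(direction = -pi / 2, spatial_freq = 2, speed = 0.5,
                        grid_size = 16, duration = 1, dt = 0.01) {
  n <- round(duration / dt)
  ax <- seq(0, 1, length.out = grid_size)
  k <- 2 * pi * spatial_freq * c(cos(direction), sin(direction))
  w <- 2 * pi * spatial_freq * speed
  out <- array(NA_real_, c(n, grid_size, grid_size))
  phase_xy <- outer(ax * k[1], ax * k[2], `+`)
  for (s in seq_len(n)) out[s, , ] <- sin(phase_xy - w * s * dt)
  out
}

#' Save / load experiment configurations
#'
#' JSON round-trip of a flat configuration list (numbers, strings, vectors).
#'
#' @param config named list.
#' @param path file path.
#' @return `load_config` returns the list.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
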