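#' Normalized root-mean-square error
#'
#' RMSE between an estimate and a reference, normalized by the RMS of the
#' mean-centred reference.  Used throughout to score decoded signals against
#' their ideal counterparts.
#'
#' @param estimate numeric vector or matrix of estimates.
#' @param truth reference values, same shape as `estimate`.
#' @return scalar NRMSE.
#' @export
nrmse <- function(estimate, truth) {
  stopifnot(length(estimate) == length(truth))
  err <- as.numeric(estimate) - as.numeric(truth)
  denom <- sqrt(mean((as.numeric(truth) - mean(truth))^2))
  if (denom == 0) denom <- max(abs(truth), 1e-12)
  sqrt(mean(err^2)) / denom
}

# Trapezoidal quadrature weights for a uniform grid of n points, spacing dt.
trapz_weights <- function(n, dt) {
  if (n == 1L) return(dt)
  w <- rep(dt, n)
  w[c(1L, n)] <- dt / 2
  w
}

# Draw a matrix of unit row vectors uniformly on the (d-1)-sphere.
random_unit_vectors <- function(n, d) {
  m <- matrix(stats::rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

#' Band-limited noise signal
#'
#' White Gaussian noise sharply low-passed in the frequency domain, scaled to
#' a target RMS.  The default probe signal for temporal weight solving and
#' the torque source for the pendulum task.
#'
#' @param duration length of the signal (s).
#' @param dt sample spacing (s).
#' @param bandwidth cutoff frequency (Hz); all energy above it is removed.
#' @param rms target root-mean-square amplitude.
#' @param seed optional integer seed.
#' @return numeric vector of `round(duration/dt)` samples.
#' @export
bandlimited_noise <- function(duration, dt, bandwidth = 5, rms = 1,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- max(2L, round(duration / dt))
  x <- stats::rnorm(n)
  f <- stats::fft(x)
  freqs <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / (n * dt)
  f[abs(freqs) > bandwidth] <- 0
  y <- Re(stats::fft(f, inverse = TRUE)) / n
  y <- y - mean(y)
  s <- sqrt(mean(y^2))
  if (s > 0) y <- y * rms / s
  y
}

# Fraction of spectral energy of x (sampled at dt) below `bandwidth` Hz.
spectral_energy_below <- function(x, dt, bandwidth) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  freqs <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / (n * dt)
  sum(p[abs(freqs) <= bandwidth]) / sum(p)
}
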