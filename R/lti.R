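#' Linear time-invariant basis-generating systems
#'
#' Container for `x' = A x + B u` systems whose impulse responses form a
#' function basis over a window of length `theta`.
#'
#' @param A q x q dynamics matrix (1/s).
#' @param B q x u input matrix (1/s).
#' @param theta window length (s).
#' @param label one of "LDN", "MF", "custom".
#' @return object of class `lti_system`.
#' @export
lti_system <- function(A, B, theta, label = "custom") {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == ncol(A), nrow(B) == nrow(A), theta > 0,
            all(is.finite(A)), all(is.finite(B)))
  structure(list(A = A, B = B, theta = theta, q = nrow(A), label = label),
            class = "lti_system")
}

#' @export
print.lti_system <- function(x, ...) {
  cat(sprintf("<lti_system %s: q = %d, theta = %g s>\n", x$label, x$q,
              x$theta))
  invisible(x)
}

#' Legendre Delay Network state-space realization
#'
#' The q-dimensional LTI system that optimally compresses the last `theta`
#' seconds of its input; its impulse responses approximate the shifted
#' Legendre polynomials on `[0, theta]`.  Uses the closed form
#' `A[i,j] = (2i+1)/theta * (-1 if i < j else (-1)^(i-j+1))`,
#' `B[i] = (2i+1) (-1)^i / theta` (zero-based indices), which for q = 1
#' coincides with the [0/1] Pade approximant of the pure delay.
#'
#' @param q system order (>= 1).
#' @param theta window length (s).
#' @return an [lti_system()] labelled "LDN".
#' @export
make_ldn <- function(q, theta) {
  stopifnot(q >= 1, theta > 0)
  i <- 0:(q - 1)
  A <- matrix(0, q, q)
  for (r in seq_len(q)) {
    for (cc in seq_len(q)) {
      ri <- r - 1; ci <- cc - 1
      A[r, cc] <- (2 * ri + 1) / theta *
        (if (ri < ci) -1 else (-1)^(ri - ci + 1))
    }
  }
  B <- matrix((2 * i + 1) * (-1)^i / theta, q, 1)
  lti_system(A, B, theta, "LDN")
}

#' Modified Fourier basis system
#'
#' An LTI system whose impulse responses span a (damped) Fourier series on
#' the window: one real low-pass mode plus harmonic oscillator pairs at
#' frequencies `2*pi*k/theta`.  The exact damping of the published variant
#' is not fixed by theory; it is exposed as `damping` (1/s applied uniformly,
#' default `1/theta` so the basis decays on the window scale).  `q` must be
#' odd (constant mode + sine/cosine pairs).
#'
#' @param q odd system order.
#' @param theta window length (s).
#' @param damping uniform decay rate (1/s).
#' @return an [lti_system()] labelled "MF".
#' @export
make_modified_fourier <- function(q, theta, damping = 1 / theta) {
  stopifnot(q >= 1, q %% 2 == 1, theta > 0)
  A <- matrix(0, q, q)
  B <- matrix(0, q, 1)
  B[1, 1] <- 1 / theta
  n_pairs <- (q - 1) / 2
  for (k in seq_len(n_pairs)) {
    w <- 2 * pi * k / theta
    idx <- 2 * k
    A[idx, idx + 1] <- w
    A[idx + 1, idx] <- -w
    B[idx, 1] <- 2 / theta
  }
  A <- A - damping * diag(q)
  lti_system(A, B, theta, "MF")
}

#' Zero-order-hold discretization
#'
#' One-step update matrices `(Ad, Bd)` such that
#' `x[k+1] = Ad x[k] + Bd u[k]` exactly when u is constant over each step;
#' computed with the augmented matrix exponential.
#'
#' @param sys an [lti_system()].
#' @param dt step size (s), > 0.
#' @return list(Ad, Bd).
#' @export
discretize_lti <- function(sys, dt) {
  stopifnot(dt > 0)
  q <- sys$q; u <- ncol(sys$B)
  M <- rbind(cbind(sys$A, sys$B), matrix(0, u, q + u)) * dt
  E <- as.matrix(Matrix::expm(M))
  list(Ad = E[seq_len(q), seq_len(q), drop = FALSE],
       Bd = E[seq_len(q), q + seq_len(u), drop = FALSE])
}

#' Impulse response of an LTI system
#'
#' Response of the state to a unit-mass impulse at t = 0, i.e.
#' `x(t) = expm(A t) B`, evaluated on a uniform time grid by exact ZOH
#' stepping (t = 0 returns `B` itself).
#'
#' @param sys an [lti_system()].
#' @param t_grid increasing, uniformly spaced times starting at 0.
#' @return length(t_grid) x q matrix of state responses.
#' @export
impulse_response <- function(sys, t_grid) {
  stopifnot(length(t_grid) >= 2, t_grid[1] == 0)
  dt <- diff(t_grid)
  stopifnot(all(abs(dt - dt[1]) < 1e-12 * max(dt)), dt[1] > 0)
  Ad <- discretize_lti(sys, dt[1])$Ad
  out <- matrix(NA_real_, length(t_grid), sys$q)
  x <- as.numeric(sys$B)
  out[1, ] <- x
  for (k in 2:length(t_grid)) {
    x <- as.numeric(Ad %*% x)
    out[k, ] <- x
    if (any(!is.finite(x))) stop("unstable integration: reduce step size")
  }
  out
}

# Shifted Legendre polynomials P~_i(r), r in [0, 1], zero-based order i,
# evaluated for orders 0..(q-1).  Returns length(r) x q matrix.
shifted_legendre <- function(q, r) {
  out <- matrix(0, length(r), q)
  x <- 2 * r - 1                      # standard Legendre argument
  out[, 1] <- 1
  if (q >= 2) out[, 2] <- x
  if (q >= 3) {
    for (i in 2:(q - 1)) {            # Bonnet recursion
      out[, i + 1] <- ((2 * i - 1) * x * out[, i] -
                         (i - 1) * out[, i - 1]) / i
    }
  }
  out
}

#' Delay readout weights and decoding
#'
#' For the LDN, the state components approximate the shifted-Legendre
#' coefficients of the input over the sliding window, so the input delayed by
#' `theta_prime` is read out with weights `d_i = P~_i(theta_prime / theta)`
#' (shifted Legendre polynomials on `[0, 1]`).
#'
#' @param sys an LDN [lti_system()].
#' @param theta_prime delay at which to reconstruct, in `[0, theta]`.
#' @return q-vector of readout weights.
#' @export
delay_readout <- function(sys, theta_prime) {
  stopifnot(theta_prime >= 0, theta_prime <= sys$theta)
  if (sys$label != "LDN")
    stop("delay readout is defined for the LDN realization")
  as.numeric(shifted_legendre(sys$q, theta_prime / sys$theta))
}

#' @rdname delay_readout
#' @param state q-vector (current LDN state) or T x q matrix of states.
#' @return scalar (or length-T vector) estimate of `u(t - theta_prime)`.
#' @export
delay_decode <- function(state, theta_prime, sys) {
  w <- delay_readout(sys, theta_prime)
  if (is.matrix(state)) as.numeric(state %*% w) else sum(state * w)
}

# Run an LTI system over an input signal (vector or T x u matrix) with ZOH
# stepping; returns T x q state trajectory (state after each step).
lti_simulate <- function(sys, u, dt, x0 = NULL) {
  u <- as.matrix(u)
  dd <- discretize_lti(sys, dt)
  x <- if (is.null(x0)) numeric(sys$q) else as.numeric(x0)
  out <- matrix(NA_real_, nrow(u), sys$q)
  for (k in seq_len(nrow(u))) {
    x <- as.numeric(dd$Ad %*% x + dd$Bd %*% u[k, ])
    out[k, ] <- x
  }
  out
}
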