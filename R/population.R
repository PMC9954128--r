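#' Create a neural population
#'
#' A population of `n` neurons representing a `dim`-dimensional variable.
#' Each neuron i has a unit-norm encoder (preferred direction) e_i, a gain
#' alpha_i and a bias current beta_i; its rate for stimulus x is
#' `G[alpha_i * <e_i, x> + beta_i]` with G the neuron model's rate function.
#' Gains and biases are derived from sampled maximum rates and intercepts,
#' mirroring how tuning curves are matched to observed response properties.
#'
#' @param n number of neurons (>= 1).
#' @param dim represented dimensionality.
#' @param encoders optional n x dim matrix; rows are normalized. Defaults to
#'   uniform random unit vectors (for dim = 1, random signs).
#' @param max_rates length-n vector or range c(lo, hi) sampled uniformly;
#'   default `c(100, 200)` Hz.
#' @param intercepts length-n vector or range sampled uniformly; default
#'   `c(-1, 1)`.
#' @param neuron neuron model, e.g. [lif_params()].
#' @param radius scale of the represented domain; stimuli are encoded as
#'   x / radius.
#' @param seed optional seed for sampling encoders/rates/intercepts.
#' @return object of class `population`.
#' @export
population <- function(n, dim, encoders = NULL, max_rates = c(100, 200),
                       intercepts = c(-1, 1), neuron = lif_params(),
                       radius = 1, seed = NULL) {
  stopifnot(n >= 1, dim >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(encoders)) {
    encoders <- if (dim == 1L) {
      matrix(sample(c(-1, 1), n, replace = TRUE), n, 1)
    } else {
      random_unit_vectors(n, dim)
    }
  } else {
    encoders <- matrix(encoders, n, dim)
    nrm <- sqrt(rowSums(encoders^2))
    stopifnot(all(nrm > 0))
    encoders <- encoders / nrm
  }
  if (length(max_rates) == 2L && n != 2L)
    max_rates <- stats::runif(n, max_rates[1], max_rates[2])
  if (length(intercepts) == 2L && n != 2L)
    intercepts <- stats::runif(n, intercepts[1], intercepts[2] - 1e-9)
  gb <- solve_gain_bias(max_rates, intercepts, neuron)
  structure(list(n = n, dim = dim, encoders = encoders, gains = gb$gain,
                 biases = gb$bias, max_rates = max_rates,
                 intercepts = intercepts, neuron = neuron, radius = radius,
                 temporal = NULL),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population: %d %s neurons, dim %d%s>\n", x$n, x$neuron$type,
              x$dim, if (!is.null(x$temporal)) ", temporal encoders" else ""))
  invisible(x)
}

# Input currents for stimulus x (dim-vector) or matrix of stimuli (N x dim).
population_currents <- function(pop, x) {
  x <- if (is.matrix(x)) t(x) else matrix(x, pop$dim, 1)
  stopifnot(nrow(x) == pop$dim)
  sweep(pop$gains * (pop$encoders %*% (x / pop$radius)), 1, pop$biases, `+`)
}

#' Static tuning curves
#'
#' Firing rates of every neuron in a population for one stimulus or a batch
#' of stimuli, through the linear-nonlinear model
#' `G[alpha_i <e_i, x> + beta_i]`.
#'
#' @param pop a [population()].
#' @param x stimulus vector of length `pop$dim`, or an N x dim matrix.
#' @return n-vector of rates (Hz), or n x N matrix for a batch.
#' @export
static_tuning <- function(pop, x) {
  J <- population_currents(pop, x)
  r <- lif_rate(J, pop$neuron)
  if (ncol(J) == 1L) as.numeric(r) else r
}

#' Attach temporal encoders to a population
#'
#' Temporal encoders generalize preferred directions to preferred stimulus
#' *histories*: each neuron's input current is the (trapezoidal) inner
#' product of its lag kernel e_i(tau) with the recent stimulus history,
#' evaluated on a shared lag grid.  Kernels are defined for lags >= 0 only
#' (causality) and are L2-normalized on the window by default.
#'
#' @param pop a [population()].
#' @param kernels n x L matrix (dim = 1) or n x L x dim array of kernel
#'   samples at lags `(0:(L-1)) * dt`.
#' @param dt lag-grid spacing (s).
#' @param normalize L2-normalize each kernel over the window (default TRUE).
#' @return the population with `temporal` field set.
#' @export
set_temporal_encoders <- function(pop, kernels, dt, normalize = TRUE) {
  if (length(dim(kernels)) == 2L) {
    kernels <- array(kernels, c(nrow(kernels), ncol(kernels), 1L))
  }
  stopifnot(length(dim(kernels)) == 3L, dim(kernels)[1] == pop$n,
            dim(kernels)[3] == pop$dim)
  L <- dim(kernels)[2]
  w <- trapz_weights(L, dt)
  if (normalize) {
    for (i in seq_len(pop$n)) {
      e <- matrix(kernels[i, , ], L, pop$dim)
      nrm <- sqrt(sum(w * rowSums(e^2)))
      if (nrm > 0) kernels[i, , ] <- kernels[i, , ] / nrm
    }
  }
  pop$temporal <- list(kernels = kernels, dt = dt, L = L, weights = w)
  pop
}

#' Temporal tuning: rates from a stimulus history
#'
#' Current of neuron i is `alpha_i * sum_tau w_tau <e_i(tau), x(t - tau)> +
#' beta_i` with trapezoidal lag weights w; the rate is `G` of that current.
#'
#' @param pop population with temporal encoders.
#' @param history L x dim matrix (or length-L vector for dim = 1); row k is
#'   the stimulus at lag `(k-1) * dt`, i.e. row 1 is the present.
#' @return n-vector of rates (Hz).
#' @export
temporal_tuning <- function(pop, history) {
  tp <- pop$temporal
  if (is.null(tp)) stop("population has no temporal encoders")
  history <- matrix(history, tp$L, pop$dim)
  J <- temporal_currents(pop, history)
  as.numeric(lif_rate(J, pop$neuron))
}

# Currents for a single history (L x dim).
temporal_currents <- function(pop, history) {
  tp <- pop$temporal
  hw <- history * tp$weights        # recycle weights down rows
  # inner product per neuron: sum over lags and stimulus dims
  acc <- numeric(pop$n)
  for (k in seq_len(pop$dim)) {
    acc <- acc + tp$kernels[, , k] %*% hw[, k]
  }
  pop$gains * as.numeric(acc) + pop$biases
}
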