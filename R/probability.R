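#' Quasi-probability density from SSP-encoded data
#'
#' Kernel density estimation in the SSP feature space: the memory vector is
#' the mean of the encoded samples, and the raw quasi-probability of a query
#' point is the dot product of its encoding with the memory — the induced
#' (sinc-like) kernel KDE.  Because the kernel takes negative values, a
#' ReLU-with-offset correction converts quasi-probabilities to a proper
#' density: `P(x) = max(0, memory . phi(x) - xi)`, with `xi` solved by
#' monotone root finding so the density integrates to 1 on the support.
#'
#' @param space an [ssp_space()].
#' @param data n x m matrix (or vector) of samples.
#' @param support optional 2 x m matrix (rows: lower, upper) for the
#'   normalisation quadrature; defaults to the data bounding box padded by 3
#'   length scales.
#' @param resolution quadrature points per dimension (default 200).
#' @return object of class `quasi_density` with `memory`, `xi`, `n`,
#'   `support`, and the quadrature grid.
#' @export
fit_quasi_density <- function(space, data, support = NULL,
                              resolution = 200) {
  data <- matrix(data, ncol = space$m)
  n <- nrow(data)
  if (n == 0) stop("no data")
  memory <- colMeans(ssp_encode_many(space, data))
  if (is.null(support)) {
    bb <- apply(data, 2, range)
    support <- rbind(bb[1, ] - 3 * space$length_scale,
                     bb[2, ] + 3 * space$length_scale)
  }
  support <- matrix(support, 2, space$m)
  axes <- lapply(seq_len(space$m), function(j)
    seq(support[1, j], support[2, j], length.out = resolution))
  grid <- as.matrix(expand.grid(axes))
  cell <- prod(sapply(axes, function(a) a[2] - a[1]))
  # the unit-norm encodings give k(0) = 1; the kernel density scale is
  # 1 / length_scale^m (the sinc KDE normalisation), applied before the
  # offset correction so xi remains a small offset
  scale <- space$length_scale^(-space$m)
  raw <- as.numeric(ssp_encode_many(space, grid) %*% memory) * scale
  # integral of max(0, raw - xi) is continuous, strictly decreasing in xi
  # until it reaches 0, so the unit-mass root is unique
  f <- function(xi) sum(pmax(0, raw - xi)) * cell - 1
  lo <- min(raw) - 1 / (cell * length(raw))    # guarantees f(lo) > 0
  hi <- max(raw)                               # f(hi) <= -1 < 0
  xi <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  structure(list(memory = memory, xi = xi, n = n, space = space,
                 scale = scale, support = support, grid = grid, cell = cell,
                 raw = raw),
            class = "quasi_density")
}

#' @export
print.quasi_density <- function(x, ...) {
  cat(sprintf("<quasi_density: n = %d, d = %d, xi = %.4f>\n", x$n,
              x$space$d, x$xi))
  invisible(x)
}

#' Evaluate a corrected quasi-probability density
#'
#' `P(x) = max(0, memory . phi(x) - xi)`: the rectified, normalised kernel
#' similarity — the response of a ReLU neuron whose weights are the memory
#' vector and whose bias is the correction offset.
#'
#' @param qd a [fit_quasi_density()] object.
#' @param x m-vector, or N x m matrix of query points.
#' @return density value(s), nonnegative.
#' @export
evaluate_density <- function(qd, x) {
  x <- matrix(x, ncol = qd$space$m)
  raw <- as.numeric(ssp_encode_many(qd$space, x) %*% qd$memory) * qd$scale
  pmax(0, raw - qd$xi)
}

# Brute-force sinc-kernel KDE (Fourier integral estimator) used as the
# independent reference for the SSP estimator in tests.
sinc_kde <- function(data, x, length_scale) {
  sapply(x, function(q) {
    u <- (q - data) / length_scale
    mean(ifelse(u == 0, 1, sin(pi * u) / (pi * u))) / length_scale
  })
}
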