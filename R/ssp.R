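#' Spatial Semantic Pointer encoding space
#'
#' Fractional power encoding of an m-dimensional continuous variable into a
#' d-dimensional unit vector: `phi(x) = IDFT[exp(i A x)]`, with the phase
#' matrix `A` (d x m) arranged with conjugate symmetry and a zero-frequency
#' row so every encoded vector is real.  `random` spaces draw the free phase
#' slopes uniformly in `[-pi, pi]^m / length_scale` (inducing a sinc-product
#' similarity kernel); `hex` spaces (m = 2) build them from triplets of plane
#' waves 120 degrees apart across geometrically spaced scale modules and a
#' set of orientations, giving hexagonal interference patterns.
#'
#' @param d SSP dimensionality; must be odd.  For `hex`, defaults to
#'   `6 * n_scales * n_rotations + 1`.
#' @param m base dimensionality (1, 2 or 3).
#' @param kind "random" or "hex".
#' @param length_scale spatial units per unit phase scaling (kernel width).
#' @param seed optional seed.
#' @param n_scales,n_rotations hex module layout.
#' @param scale_range multiplicative range of hex module wavelengths
#'   relative to `length_scale`.
#' @return object of class `ssp_space` with fields `A` (d x m full phase
#'   matrix), `freq` (free rows index), `d`, `m`.
#' @export
ssp_space <- function(d = NULL, m = 1, kind = c("random", "hex"),
                      length_scale = 0.5, seed = NULL, n_scales = 5,
                      n_rotations = 5, scale_range = c(1, 3)) {
  kind <- match.arg(kind)
  stopifnot(m >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (kind == "hex") {
    stopifnot(m == 2)
    n_free_needed <- 3L * n_scales * n_rotations
    if (is.null(d)) d <- 2L * n_free_needed + 1L
    stopifnot(d %% 2 == 1, (d - 1) / 2 == n_free_needed)
    scales <- exp(seq(log(scale_range[1]), log(scale_range[2]),
                      length.out = n_scales))
    rot <- stats::runif(n_rotations, 0, 2 * pi / 3)
    phases <- NULL
    modules <- integer(0)
    mod_id <- 0L
    for (s in scales) {
      for (r in rot) {
        mod_id <- mod_id + 1L
        k <- 2 * pi / (3 * length_scale * s)   # wave number of the module
        ang <- r + c(0, 2 * pi / 3, 4 * pi / 3)
        tri <- k * cbind(cos(ang), sin(ang))
        phases <- rbind(phases, tri)
        modules <- c(modules, rep(mod_id, 3L))
      }
    }
  } else {
    if (is.null(d)) d <- 101L
    stopifnot(d %% 2 == 1)
    n_free <- (d - 1L) / 2L
    if (m == 1) {
      # stratified (jittered-grid) sample of the uniform spectral density:
      # same limiting sinc kernel as iid sampling, far less ripple
      w <- 2 * pi / (length_scale * n_free)
      phases <- matrix(-pi / length_scale + (seq_len(n_free) - 1) * w +
                         stats::runif(n_free) * w, n_free, 1)
    } else {
      phases <- matrix(stats::runif(n_free * m, -pi, pi) / length_scale,
                       n_free, m)
    }
    modules <- NULL
  }
  n_free <- nrow(phases)
  # full phase matrix: row 1 is the zero-frequency term; rows 2..n_free+1
  # are free; the remainder are the negated mirror (conjugate symmetry)
  A <- rbind(matrix(0, 1, m), phases,
             -phases[rev(seq_len(n_free)), , drop = FALSE])
  structure(list(A = A, d = d, m = m, kind = kind,
                 length_scale = length_scale, free = 1 + seq_len(n_free),
                 modules = modules,
                 n_scales = if (kind == "hex") n_scales else NULL,
                 n_rotations = if (kind == "hex") n_rotations else NULL),
            class = "ssp_space")
}

#' @export
print.ssp_space <- function(x, ...) {
  cat(sprintf("<ssp_space %s: d = %d, m = %d, length_scale = %g>\n", x$kind,
              x$d, x$m, x$length_scale))
  invisible(x)
}

# Inverse DFT of a conjugate-symmetric phasor vector; returns a real vector.
idft_real <- function(F) {
  Re(stats::fft(F, inverse = TRUE)) / length(F)
}

#' Encode a point as a Spatial Semantic Pointer
#'
#' `phi(x) = IDFT[exp(i A x)]`: a real, unit-norm d-vector.  `ssp_encode_many`
#' encodes the rows of a matrix at once.
#'
#' @param space an [ssp_space()].
#' @param x m-vector (finite).
#' @return d-vector (unit norm).
#' @export
ssp_encode <- function(space, x) {
  stopifnot(length(x) == space$m, all(is.finite(x)))
  idft_real(exp(1i * as.numeric(space$A %*% x)))
}

#' @rdname ssp_encode
#' @param X N x m matrix of points.
#' @return N x d matrix whose rows are SSPs.
#' @export
ssp_encode_many <- function(space, X) {
  X <- matrix(X, ncol = space$m)
  Fm <- exp(1i * (space$A %*% t(X)))          # d x N phasors
  t(Re(stats::mvfft(Fm, inverse = TRUE)) / space$d)
}

#' Binding and unbinding (circular convolution)
#'
#' Binding is circular convolution, computed as an elementwise product in the
#' Fourier domain; phases add, so `bind(phi(x), phi(y)) = phi(x + y)`.
#' Unbinding binds with the involution (conjugate spectrum) of `b` and is the
#' exact inverse when `b` is unitary (all Fourier magnitudes 1).
#'
#' @param a,b real vectors of equal length.
#' @return real vector of the same length.
#' @export
ssp_bind <- function(a, b) {
  stopifnot(length(a) == length(b))
  idft_real(stats::fft(a) * stats::fft(b))
}

#' @rdname ssp_bind
#' @export
ssp_unbind <- function(a, b) {
  stopifnot(length(a) == length(b))
  idft_real(stats::fft(a) * Conj(stats::fft(b)))
}

#' Similarity kernel induced by an SSP space
#'
#' Dot product of encodings; by construction it depends only on `x - xp`
#' (shift invariance).  For random 1-D spaces it approaches
#' `sinc((x - xp)/length_scale)` as d grows.
#'
#' @param space an [ssp_space()].
#' @param x,xp m-vectors.
#' @return scalar similarity.
#' @export
induced_kernel <- function(space, x, xp) {
  sum(ssp_encode(space, x) * ssp_encode(space, xp))
}

#' Decode a point from an SSP
#'
#' Grid argmax of the similarity with `phi` over a coarse grid followed by
#' quasi-Newton refinement of the (differentiable) similarity in the Fourier
#' domain.  Vectors far from the SSP manifold are flagged unreliable.
#'
#' @param space an [ssp_space()].
#' @param v d-vector (a possibly noisy SSP).
#' @param lower,upper m-vectors bounding the search box.
#' @param resolution coarse grid points per dimension.
#' @param threshold peak similarity below which the result is flagged.
#' @return list(x = m-vector estimate, similarity = peak value,
#'   reliable = logical).
#' @export
ssp_decode <- function(space, v, lower = rep(-5, space$m),
                       upper = rep(5, space$m), resolution = 51,
                       threshold = 0.25) {
  axes <- lapply(seq_len(space$m), function(j)
    seq(lower[j], upper[j], length.out = resolution))
  grid <- as.matrix(expand.grid(axes))
  sims <- as.numeric(ssp_encode_many(space, grid) %*% v)
  x0 <- grid[which.max(sims), ]
  Fv <- Conj(stats::fft(v))                    # for s(x) = Re(sum Fv e^{iAx})/d
  obj <- function(x) {
    ph <- exp(1i * as.numeric(space$A %*% x))
    -Re(sum(Fv * ph)) / space$d
  }
  grad <- function(x) {
    ph <- exp(1i * as.numeric(space$A %*% x))
    g <- -Re(crossprod(space$A, 1i * Fv * ph)) / space$d
    as.numeric(g)
  }
  opt <- stats::optim(x0, obj, grad, method = "BFGS",
                      control = list(maxit = 100))
  list(x = as.numeric(opt$par), similarity = -opt$value,
       reliable = -opt$value >= threshold)
}
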