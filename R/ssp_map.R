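#' Concept vocabulary of unitary vectors
#'
#' Named random unitary d-vectors (all Fourier magnitudes 1) used as concept
#' tags in slot-filler structures; unitarity makes unbinding exact.
#'
#' @param names character vector of concept names.
#' @param d vector dimensionality (odd).
#' @param seed optional seed.
#' @return object of class `ssp_vocabulary` (a named list of d-vectors).
#' @export
make_vocabulary <- function(names, d, seed = NULL) {
  stopifnot(d %% 2 == 1)
  if (!is.null(seed)) set.seed(seed)
  n_free <- (d - 1) / 2
  vecs <- lapply(names, function(nm) {
    ph <- stats::runif(n_free, -pi, pi)
    full <- c(0, ph, -rev(ph))
    idft_real(exp(1i * full))
  })
  names(vecs) <- names
  structure(vecs, class = "ssp_vocabulary")
}

#' Integrate the SSP encoding over a region
#'
#' Numerical quadrature of `phi` over a polygon (or explicit sample set):
#' a uniform grid of spacing at most `length_scale / 4` is laid over the
#' bounding box, interior points are kept, and their encodings are summed
#' with the cell area as quadrature weight.
#'
#' @param space an [ssp_space()] with m = 2 (or m = 1 with an interval).
#' @param region for m = 2, a polygon as an n x 2 vertex matrix; for m = 1,
#'   `c(lo, hi)`.  Alternatively a matrix of sample points with attribute
#'   `weight`.
#' @param spacing quadrature grid spacing; default `length_scale / 4`.
#' @param normalize divide by total area (density convention) instead of
#'   keeping total mass; default FALSE.
#' @return d-vector.
#' @export
encode_region <- function(space, region, spacing = space$length_scale / 4,
                          normalize = FALSE) {
  if (space$m == 1) {
    stopifnot(length(region) == 2, diff(region) > 0)
    xs <- seq(region[1], region[2], by = spacing)
    pts <- matrix(xs, ncol = 1)
    w <- spacing
  } else {
    region <- as.matrix(region)
    stopifnot(ncol(region) == space$m)
    bb <- apply(region, 2, range)
    if (any(bb[2, ] - bb[1, ] <= 0)) stop("region has no area")
    xs <- seq(bb[1, 1], bb[2, 1], by = spacing)
    ys <- seq(bb[1, 2], bb[2, 2], by = spacing)
    grid <- as.matrix(expand.grid(xs, ys))
    inside <- pracma::inpolygon(grid[, 1], grid[, 2],
                                region[, 1], region[, 2],
                                boundary = TRUE)
    if (!any(inside)) stop("region has no interior quadrature points")
    pts <- grid[inside, , drop = FALSE]
    w <- spacing^2
  }
  v <- colSums(ssp_encode_many(space, pts)) * w
  if (normalize) v <- v / (nrow(pts) * w)
  v
}

#' Build an environment map vector
#'
#' Sums concept-bound location encodings: each item binds a vocabulary
#' concept with the SSP of a point, the sum of SSPs of a point set, or a
#' region integral, yielding a single vector representing the whole
#' environment.
#'
#' @param space an [ssp_space()].
#' @param vocab an [ssp_vocabulary()][make_vocabulary()].
#' @param items list of items, each a list with `concept` (name in vocab) and
#'   one of `location` (m-vector or N x m matrix of locations) or `region`
#'   (polygon vertices, see [encode_region()]).
#' @return object of class `environment_map` with the sum vector `E` and the
#'   item declarations.
#' @export
build_map <- function(space, vocab, items) {
  E <- numeric(space$d)
  for (it in items) {
    if (!it$concept %in% names(vocab)) stop("unknown concept: ", it$concept)
    enc <- if (!is.null(it$region)) {
      encode_region(space, it$region)
    } else {
      loc <- matrix(it$location, ncol = space$m)
      colSums(ssp_encode_many(space, loc))
    }
    E <- E + ssp_bind(vocab[[it$concept]], enc)
  }
  structure(list(E = E, items = items, space = space, vocab = vocab),
            class = "environment_map")
}

#' Query a map for a concept's location(s)
#'
#' Unbinds the concept from the map vector and evaluates the similarity of
#' the result with SSP encodings over a grid, producing a heat map whose
#' peaks mark the concept's stored locations.
#'
#' @param map an [environment_map()][build_map()].
#' @param concept concept name.
#' @param xlim,ylim grid extent.
#' @param resolution grid points per axis.
#' @return list with `x`, `y` axes, `sim` matrix (length(x) x length(y)), and
#'   `query` (the unbound vector).
#' @export
query_map <- function(map, concept, xlim = c(-5, 5), ylim = c(-5, 5),
                      resolution = 101) {
  space <- map$space
  Q <- ssp_unbind(map$E, map$vocab[[concept]])
  if (space$m == 1) {
    xs <- seq(xlim[1], xlim[2], length.out = resolution)
    sims <- as.numeric(ssp_encode_many(space, matrix(xs)) %*% Q)
    return(list(x = xs, sim = sims, query = Q))
  }
  xs <- seq(xlim[1], xlim[2], length.out = resolution)
  ys <- seq(ylim[1], ylim[2], length.out = resolution)
  grid <- as.matrix(expand.grid(xs, ys))
  sims <- matrix(as.numeric(ssp_encode_many(space, grid) %*% Q),
                 length(xs), length(ys))
  list(x = xs, y = ys, sim = sims, query = Q)
}

# Local maxima of a 2-D similarity surface above a threshold, as an n x 2
# matrix of (x, y) peak locations.
find_peaks <- function(qm, threshold) {
  s <- qm$sim
  nx <- nrow(s); ny <- ncol(s)
  peaks <- NULL
  for (i in 2:(nx - 1)) {
    for (j in 2:(ny - 1)) {
      v <- s[i, j]
      if (v < threshold) next
      nb <- s[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (v >= max(nb)) peaks <- rbind(peaks, c(qm$x[i], qm$y[j], v))
    }
  }
  peaks
}
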