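#' Grid cell population over a hexagonal SSP space
#'
#' Encoders are built per neuron from a single hex module's plane-wave
#' triplet with a random spatial phase offset: in the Fourier domain the
#' encoder is nonzero only on that module's frequency bins (and their
#' conjugates), with phases `exp(-i a_j . x0)`, so the neuron's input current
#' is a three-plane-wave interference pattern centred on `x0` — a hexagonal
#' grid whose scale and orientation come from the module.  Intercepts are set
#' per neuron from the empirical distribution of encoder-SSP similarities so
#' that approximately `sparsity` of neurons are suprathreshold at a random
#' location (the bias-current route to sparse coding).
#'
#' @param space a hex [ssp_space()].
#' @param n number of neurons.
#' @param sparsity target active fraction in (0, 1].
#' @param extent half-width of the square region used to calibrate
#'   intercepts.
#' @param max_rates sampled uniformly from this range (Hz).
#' @param neuron neuron model.
#' @param seed optional seed.
#' @return a [population()] with `dim = space$d`; extra fields `space` and
#'   `module` (module index per neuron).
#' @export
grid_cell_population <- function(space, n, sparsity = 0.2, extent = 5,
                                 max_rates = c(100, 200),
                                 neuron = lif_params(), seed = NULL) {
  stopifnot(space$kind == "hex", sparsity > 0, sparsity <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_modules <- max(space$modules)
  module <- sample.int(n_modules, n, replace = TRUE)
  E <- matrix(0, n, space$d)
  for (i in seq_len(n)) {
    x0 <- stats::runif(2, -extent, extent)
    Fenc <- complex(space$d)
    rows <- space$free[space$modules == module[i]]
    Fenc[rows] <- exp(-1i * as.numeric(space$A[rows, ] %*% x0))
    # conjugate-symmetric partners
    conj_rows <- space$d + 2 - rows
    Fenc[conj_rows] <- Conj(Fenc[rows])
    E[i, ] <- idft_real(Fenc)
  }
  pop <- population(n, space$d, encoders = E, max_rates = max_rates,
                    intercepts = rep(0, n), neuron = neuron)
  pop <- calibrate_sparsity(pop, space, sparsity, extent)
  pop$space <- space
  pop$module <- module
  pop
}

# Set per-neuron intercepts to the (1 - sparsity) quantile of that neuron's
# similarity with SSPs of random locations, then re-derive gains/biases.
calibrate_sparsity <- function(pop, space, sparsity, extent, n_cal = 400) {
  X <- matrix(stats::runif(n_cal * space$m, -extent, extent), n_cal, space$m)
  S <- ssp_encode_many(space, X) %*% t(pop$encoders)       # n_cal x n
  ic <- apply(S, 2, stats::quantile, probs = 1 - sparsity)
  ic <- pmin(ic, 0.999)
  gb <- solve_gain_bias(pop$max_rates, ic, pop$neuron)
  pop$intercepts <- ic
  pop$gains <- gb$gain
  pop$biases <- gb$bias
  pop
}

#' Place cell population
#'
#' Neuron j's encoder is the SSP of a preferred location; driven by the SSP
#' of the current position, its firing field is the induced kernel centred
#' at that location.
#'
#' @param space an [ssp_space()].
#' @param centres n x m matrix of field centres.
#' @param max_rates,intercepts,neuron tuning parameters; the default
#'   intercept (0.3 similarity) keeps fields compact.
#' @param seed optional seed.
#' @return a [population()] with extra field `centres`.
#' @export
place_cell_population <- function(space, centres, max_rates = c(100, 200),
                                  intercepts = c(0.2, 0.4),
                                  neuron = lif_params(), seed = NULL) {
  centres <- matrix(centres, ncol = space$m)
  if (!is.null(seed)) set.seed(seed)
  E <- ssp_encode_many(space, centres)
  pop <- population(nrow(centres), space$d, encoders = E,
                    max_rates = max_rates, intercepts = intercepts,
                    neuron = neuron)
  pop$space <- space
  pop$centres <- centres
  pop
}

#' Object-vector / border cell population
#'
#' Neurons encode SSPs of preferred *displacement* vectors; the population's
#' input is the SSP of the displacement from the agent to the nearest target
#' object (or nearest point of a wall segment).  An object-vector cell then
#' fires whenever the agent sits at its preferred offset from any object; a
#' border cell's field hugs the wall.
#'
#' @param space an [ssp_space()] (m = 2).
#' @param preferred n x 2 matrix of preferred displacement vectors; default
#'   random within `max_range`.
#' @param n number of neurons when `preferred` is NULL.
#' @param targets list with either `objects` (k x 2 matrix) or `wall`
#'   (list(point =, normal =) for an infinite wall line, or a 2 x 2 segment
#'   matrix).
#' @param max_range visibility limit (displacements are computed to the
#'   nearest target; no cutoff by default).
#' @param ... tuning arguments passed to [place_cell_population()] machinery.
#' @inheritParams place_cell_population
#' @return a [population()] with fields `targets`, `preferred`, `max_range`.
#' @export
vector_cell_population <- function(space, targets, preferred = NULL, n = 20,
                                   max_range = Inf,
                                   max_rates = c(100, 200),
                                   intercepts = c(0.2, 0.4),
                                   neuron = lif_params(), seed = NULL) {
  if (is.null(targets$objects) && is.null(targets$wall))
    stop("targets must declare objects or a wall")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(preferred))
    preferred <- matrix(stats::runif(n * 2, -2, 2), n, 2)
  pop <- place_cell_population(space, preferred, max_rates = max_rates,
                               intercepts = intercepts, neuron = neuron)
  pop$preferred <- preferred
  pop$centres <- NULL
  pop$targets <- targets
  pop$max_range <- max_range
  pop
}

#' Displacement from a position to the nearest declared target
#'
#' @param targets as in [vector_cell_population()].
#' @param x agent position (2-vector).
#' @param max_range beyond this distance the displacement is NA (nothing in
#'   view).
#' @return 2-vector displacement (target - agent), or NAs.
#' @export
nearest_displacement <- function(targets, x, max_range = Inf) {
  cand <- NULL
  if (!is.null(targets$objects)) {
    obj <- matrix(targets$objects, ncol = 2)
    d2 <- rowSums((obj - matrix(x, nrow(obj), 2, byrow = TRUE))^2)
    cand <- obj[which.min(d2), ] - x
  }
  if (!is.null(targets$wall)) {
    w <- targets$wall
    disp <- if (is.list(w)) {
      nrm <- w$normal / sqrt(sum(w$normal^2))
      as.numeric((sum((w$point - x) * nrm)) * nrm)
    } else {
      seg_displacement(w, x)
    }
    if (is.null(cand) || sum(disp^2) < sum(cand^2)) cand <- disp
  }
  if (sqrt(sum(cand^2)) > max_range) return(c(NA_real_, NA_real_))
  cand
}

# Displacement to the closest point of segment (2 x 2 matrix of endpoints).
seg_displacement <- function(seg, x) {
  a <- seg[1, ]; b <- seg[2, ]
  ab <- b - a
  t <- sum((x - a) * ab) / sum(ab^2)
  p <- a + pmin(pmax(t, 0), 1) * ab
  p - x
}

#' Spatial rate map of a population over a trajectory
#'
#' Bins a trajectory into a spatial grid and accumulates each neuron's
#' activity, dividing by occupancy time.  `mode = "rate"` uses the
#' rate-model response (fast, deterministic); `mode = "spiking"` steps the
#' spiking neuron model along the trajectory and counts spikes.  Unvisited
#' bins are NA.
#'
#' @param pop population whose `dim` matches the SSP dimensionality.
#' @param trajectory data frame or matrix with columns (t, x, y).
#' @param input_fn function(position) returning the population input vector
#'   (default: SSP encoding of position via `pop$space`; for vector cells
#'   the displacement encoding).
#' @param bin_size spatial bin width.
#' @param xlim,ylim map extent (default trajectory bounding box).
#' @param mode "rate" or "spiking".
#' @return list of class `rate_map`: `rates` (nx x ny x n array),
#'   `occupancy` (seconds per bin), `x`, `y` bin centres.
#' @export
rate_map <- function(pop, trajectory, input_fn = NULL, bin_size = 0.25,
                     xlim = NULL, ylim = NULL,
                     mode = c("rate", "spiking")) {
  mode <- match.arg(mode)
  trajectory <- as.matrix(trajectory)
  t <- trajectory[, 1]; P <- trajectory[, 2:3, drop = FALSE]
  dt <- stats::median(diff(t))
  if (is.null(xlim)) xlim <- range(P[, 1])
  if (is.null(ylim)) ylim <- range(P[, 2])
  xb <- seq(xlim[1], xlim[2] + bin_size, by = bin_size)
  yb <- seq(ylim[1], ylim[2] + bin_size, by = bin_size)
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  ix <- pmin(pmax(findInterval(P[, 1], xb), 1L), nx)
  iy <- pmin(pmax(findInterval(P[, 2], yb), 1L), ny)
  # population input per sample
  inputs <- if (is.null(input_fn)) {
    if (is.null(pop$space)) stop("population carries no SSP space; ",
                                 "supply input_fn")
    if (!is.null(pop$targets)) {
      disp <- t(apply(P, 1, function(p)
        nearest_displacement(pop$targets, p, pop$max_range)))
      enc <- matrix(0, nrow(disp), pop$space$d)   # nothing in view -> zeros
      ok <- stats::complete.cases(disp)
      if (any(ok)) enc[ok, ] <- ssp_encode_many(pop$space,
                                                disp[ok, , drop = FALSE])
      enc
    } else {
      ssp_encode_many(pop$space, P)
    }
  } else {
    t(apply(P, 1, input_fn))
  }
  acts <- if (mode == "rate") {
    t(static_tuning(pop, inputs))                 # T x n rates
  } else {
    st <- lif_state(pop$n)
    out <- matrix(0, nrow(inputs), pop$n)
    for (k in seq_len(nrow(inputs))) {
      J <- pop$gains * as.numeric(pop$encoders %*%
                                    (inputs[k, ] / pop$radius)) + pop$biases
      r <- lif_spike_step(st, J, dt, pop$neuron)
      st <- r$state
      out[k, ] <- r$spikes / dt                   # spike count / dt = Hz
    }
    out
  }
  bin <- (iy - 1L) * nx + ix
  occ <- tabulate(bin, nbins = nx * ny) * dt
  rates <- array(NA_real_, c(nx, ny, pop$n))
  for (j in seq_len(pop$n)) {
    s <- numeric(nx * ny)
    acc <- rowsum(acts[, j] * dt, bin)
    s[as.integer(rownames(acc))] <- acc
    m <- s / occ
    m[occ == 0] <- NA
    rates[, , j] <- matrix(m, nx, ny)
  }
  structure(list(rates = rates, occupancy = matrix(occ, nx, ny),
                 x = xb[-length(xb)] + bin_size / 2,
                 y = yb[-length(yb)] + bin_size / 2, bin_size = bin_size),
            class = "rate_map")
}

# Centroid of a single neuron's rate map (weighted by rate).
rate_map_centroid <- function(rm, j) {
  m <- rm$rates[, , j]
  m[is.na(m)] <- 0
  tot <- sum(m)
  if (tot == 0) return(c(NA, NA))
  c(sum(outer(rm$x, rep(1, length(rm$y))) * m),
    sum(outer(rep(1, length(rm$x)), rm$y) * m)) / tot
}

# 2-D spatial autocorrelogram of a rate map matrix (NA-tolerant, mean
# subtracted, Pearson per offset via FFT on zero-filled copies).
spatial_autocorr <- function(m) {
  m <- m - mean(m, na.rm = TRUE)
  m[is.na(m)] <- 0
  nx <- nrow(m); ny <- ncol(m)
  pad <- matrix(0, 2 * nx, 2 * ny)
  pad[1:nx, 1:ny] <- m
  F <- stats::fft(pad)
  ac <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / length(pad)
  # centre the zero offset
  ac <- ac[c((nx + 1):(2 * nx), 1:nx), c((ny + 1):(2 * ny), 1:ny)]
  ac / max(ac)
}

# Rotate a matrix about its centre by `deg` degrees (bilinear interpolation).
rotate_matrix <- function(m, deg) {
  nx <- nrow(m); ny <- ncol(m)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  th <- deg * pi / 180
  out <- matrix(NA_real_, nx, ny)
  xs <- rep(seq_len(nx), ny) - cx
  ys <- rep(seq_len(ny), each = nx) - cy
  xr <- cos(th) * xs - sin(th) * ys + cx
  yr <- sin(th) * xs + cos(th) * ys + cy
  ok <- xr >= 1 & xr <= nx & yr >= 1 & yr <= ny
  vals <- pracma::interp2(seq_len(ny), seq_len(nx), m,
                          yr[ok], xr[ok], method = "linear")
  out[which(ok)] <- vals
  out
}

#' Gridness score of a rate map
#'
#' Rotational-autocorrelation contrast: the spatial autocorrelogram is
#' rotated by 30..150 degrees and correlated (within an annulus excluding the
#' central peak) with the unrotated version; the score is
#' `min(r60, r120) - max(r30, r90, r150)`.  Positive scores indicate
#' hexagonal structure.
#'
#' @param rm a [rate_map()] or a plain matrix.
#' @param j neuron index when `rm` is a rate map.
#' @return scalar gridness score.
#' @export
gridness_score <- function(rm, j = 1) {
  m <- if (inherits(rm, "rate_map")) rm$rates[, , j] else rm
  ac <- spatial_autocorr(m)
  nx <- nrow(ac); ny <- ncol(ac)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r <- sqrt(outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, `+`))
  rmax <- min(nx, ny) / 2 - 1
  annulus <- r > rmax * 0.15 & r < rmax
  cors <- sapply(c(30, 60, 90, 120, 150), function(a) {
    rot <- rotate_matrix(ac, a)
    ok <- annulus & !is.na(rot)
    stats::cor(ac[ok], rot[ok])
  })
  min(cors[2], cors[4]) - max(cors[1], cors[3], cors[5])
}
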