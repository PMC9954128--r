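make_hex <- function(seed, ...) {
  ssp_space(m = 2, kind = "hex", length_scale = 0.4, seed = seed,
            scale_range = c(1, 2.5), ...)
}

covering_walk <- function(extent, duration = 240, seed = 72) {
  gen_trajectory_2d(arena = list(kind = "rect", width = 2 * extent,
                                 height = 2 * extent),
                    duration = duration, dt = 0.05, mean_speed = 1.5,
                    smoothness = 0.5, seed = seed)
}

test_that("grid-cell currents are three-plane-wave interference patterns", {
  hx <- make_hex(71)
  pop <- grid_cell_population(hx, 5, sparsity = 0.2, extent = 2, seed = 71)
  # the similarity of encoder i with phi(x) equals the module's cosine sum
  set.seed(71)
  for (i in 1:5) {
    rows <- hx$free[hx$modules == pop$module[i]]
    x <- runif(2, -2, 2)
    sim <- sum(pop$encoders[i, ] * ssp_encode(hx, x))
    # encoder built as idft of module-restricted phasors at offset x0;
    # reconstruct x0 from the encoder spectrum
    Fe <- fft(pop$encoders[i, ])
    ph <- Arg(Fe[rows])
    # sim = (1/d) Re sum_k conj(Fe_k) e^{i a_k x}: three cosines (plus
    # their conjugate partners) at the module wave vectors
    pred <- 2 * sum(Mod(Fe[rows]) * cos(hx$A[rows, ] %*% x - ph)) / hx$d
    expect_equal(sim, pred, tolerance = 1e-8)
  }
})

test_that("grid cells produce hexagonal rate maps on a covering walk", {
  hx <- make_hex(73)
  pop <- grid_cell_population(hx, 12, sparsity = 0.2, extent = 2.5,
                              seed = 74)
  tr <- covering_walk(2.5, seed = 75)
  rm1 <- rate_map(pop, tr, bin_size = 0.2, xlim = c(-2.5, 2.5),
                  ylim = c(-2.5, 2.5))
  gs <- sapply(1:12, function(j) gridness_score(rm1, j))
  expect_gte(mean(gs > 0), 0.8)
})

test_that("grid spacing scales linearly with the module length scale", {
  spacing_of <- function(scale) {
    hx <- ssp_space(m = 2, kind = "hex", length_scale = 0.4, seed = 76,
                    n_scales = 1, n_rotations = 1,
                    scale_range = c(scale, scale))
    g <- seq(-3, 3, 0.05)
    grid <- as.matrix(expand.grid(g, g))
    sims <- matrix(ssp_encode_many(hx, grid) %*% ssp_encode(hx, c(0, 0)),
                   length(g), length(g))
    pk <- neftools:::find_peaks(list(sim = sims, x = g, y = g), 0.9)
    r <- sqrt(rowSums(pk[, 1:2, drop = FALSE]^2))
    min(r[r > 0.1])                       # first-ring radius = lattice const
  }
  scales <- c(1, 1.5, 2)
  sp <- sapply(scales, spacing_of)
  fit <- lm(sp ~ scales)
  expect_gt(summary(fit)$r.squared, 0.9)
  expect_gt(coef(fit)[2], 0)
})

test_that("sparsity calibration hits the target active fraction", {
  hx <- make_hex(77)
  set.seed(77)
  X <- matrix(runif(400 * 2, -2, 2), 400, 2)
  E <- ssp_encode_many(hx, X[1:50, ])     # not used; just exercise encoding
  for (sp_target in c(0.1, 0.3)) {
    pop <- grid_cell_population(hx, 60, sparsity = sp_target, extent = 2,
                                seed = 78)
    acts <- static_tuning(pop, ssp_encode_many(hx, X))
    expect_equal(mean(acts > 0), sp_target, tolerance = 0.03)
  }
  # sparsity monotonicity: raising all intercepts lowers the active fraction
  pop <- grid_cell_population(hx, 60, sparsity = 0.3, extent = 2, seed = 78)
  gb <- solve_gain_bias(pop$max_rates, pmin(pop$intercepts + 0.2, 0.999),
                        pop$neuron)
  pop2 <- pop
  pop2$gains <- gb$gain
  pop2$biases <- gb$bias
  a1 <- static_tuning(pop, ssp_encode_many(hx, X))
  a2 <- static_tuning(pop2, ssp_encode_many(hx, X))
  expect_lt(mean(a2 > 0), mean(a1 > 0))
  expect_error(grid_cell_population(hx, 10, sparsity = 0))
})

test_that("place cells fire at their centres with compact fields", {
  sp <- ssp_space(d = 201, m = 2, length_scale = 0.4, seed = 79)
  centres <- rbind(c(-1, -1), c(1.5, 0.5), c(0, 1.8))
  pop <- place_cell_population(sp, centres, seed = 79)
  for (j in 1:3) {
    at_centre <- static_tuning(pop, ssp_encode(sp, centres[j, ]))[j]
    far <- static_tuning(pop, ssp_encode(sp, centres[j, ] + c(1.2, 0)))[j]
    expect_gt(at_centre, far + 20)
  }
  # distant centres have near-orthogonal encoders
  expect_lt(abs(sum(pop$encoders[1, ] * pop$encoders[2, ])), 0.15)
  # field centroid from a rate map sits near the declared centre
  tr <- covering_walk(2, duration = 200, seed = 80)
  rm1 <- rate_map(pop, tr, bin_size = 0.2, xlim = c(-2, 2), ylim = c(-2, 2))
  cen <- neftools:::rate_map_centroid(rm1, 2)
  expect_lt(sqrt(sum((cen - centres[2, ])^2)), 0.2 * 2.5)
})

test_that("object-vector cells fire at a fixed offset from objects", {
  sp <- ssp_space(d = 201, m = 2, length_scale = 0.4, seed = 81)
  objects <- rbind(c(-1, 0), c(1, 1))
  pop <- vector_cell_population(sp, list(objects = objects),
                                preferred = matrix(c(0.6, 0), 1), seed = 81)
  expect_equal(nearest_displacement(list(objects = objects), c(0.8, 0.9)),
               c(0.2, 0.1))
  expect_true(anyNA(nearest_displacement(list(objects = objects),
                                         c(0.8, 0.9), max_range = 0.1)))
  tr <- covering_walk(2, duration = 200, seed = 82)
  rm1 <- rate_map(pop, tr, bin_size = 0.2, xlim = c(-2, 2), ylim = c(-2, 2))
  m <- rm1$rates[, , 1]
  m[is.na(m)] <- 0
  # firing fields sit where object - agent = preferred, i.e. agent at
  # object - preferred
  exp_fields <- sweep(objects, 2, c(0.6, 0))
  for (k in 1:2) {
    i <- which(m == max(m), arr.ind = TRUE)[1, ]
    got <- c(rm1$x[i[1]], rm1$y[i[2]])
    d <- min(sqrt(rowSums(sweep(exp_fields, 2, got)^2)))
    expect_lt(d, 0.45)
    # suppress that field and look for the second
    sel <- outer(rm1$x, rep(1, length(rm1$y))) > got[1] - 0.5 &
      outer(rm1$x, rep(1, length(rm1$y))) < got[1] + 0.5 &
      outer(rep(1, length(rm1$x)), rm1$y) > got[2] - 0.5 &
      outer(rep(1, length(rm1$x)), rm1$y) < got[2] + 0.5
    m[sel] <- 0
  }
  # moving a single object translates its firing field equally
  one <- vector_cell_population(sp, list(objects = rbind(c(-0.5, 0))),
                                preferred = matrix(c(0.6, 0), 1), seed = 81)
  one$encoders <- pop$encoders
  rma <- rate_map(one, tr, bin_size = 0.2, xlim = c(-2, 2), ylim = c(-2, 2))
  two <- one
  two$targets <- list(objects = rbind(c(-0.5, 0) + c(0.3, 0.4)))
  rmb <- rate_map(two, tr, bin_size = 0.2, xlim = c(-2, 2), ylim = c(-2, 2))
  ca <- neftools:::rate_map_centroid(rma, 1)
  cb <- neftools:::rate_map_centroid(rmb, 1)
  expect_lt(sqrt(sum((cb - ca - c(0.3, 0.4))^2)), 0.2 * 2.5)
})

test_that("border cells hug the declared wall", {
  sp <- ssp_space(d = 201, m = 2, length_scale = 0.4, seed = 83)
  # wall along the right side of the environment (x = 2)
  pop <- vector_cell_population(sp, list(wall = list(point = c(2, 0),
                                                     normal = c(1, 0))),
                                preferred = matrix(c(0.4, 0), 1), seed = 83)
  tr <- covering_walk(2, duration = 200, seed = 84)
  rm1 <- rate_map(pop, tr, bin_size = 0.2, xlim = c(-2, 2), ylim = c(-2, 2))
  m <- rm1$rates[, , 1]
  m[is.na(m)] <- 0
  occ_rate <- rowSums(m)
  # activity mass concentrated in the band x ~ 1.6 next to the wall
  band <- rm1$x > 1.2
  expect_gt(sum(occ_rate[band]), 0.8 * sum(occ_rate))
  expect_error(vector_cell_population(sp, list(), seed = 1))
})

test_that("rate maps bin correctly and respect occupancy", {
  sp <- ssp_space(d = 101, m = 2, length_scale = 0.4, seed = 85)
  pop <- place_cell_population(sp, rbind(c(0, 0)), seed = 85)
  # constant input: flat map
  tr <- covering_walk(1.5, duration = 100, seed = 86)
  rmc <- rate_map(pop, tr, input_fn = function(p) ssp_encode(sp, c(0, 0)),
                  bin_size = 0.25, xlim = c(-1.5, 1.5), ylim = c(-1.5, 1.5))
  vals <- rmc$rates[, , 1]
  vals <- vals[!is.na(vals)]
  expect_lt(diff(range(vals)), 1e-9)
  # unvisited bins are NA
  tr2 <- tr
  tr2[, 2:3] <- abs(as.matrix(tr2[, 2:3]))    # fold into one quadrant
  rmq <- rate_map(pop, tr2, bin_size = 0.25, xlim = c(-1.5, 1.5),
                  ylim = c(-1.5, 1.5))
  expect_true(anyNA(rmq$rates[1, 1, ]))      # far corner never visited
  # halving bin size keeps the field centroid within one (coarse) bin
  rma <- rate_map(pop, tr, bin_size = 0.25, xlim = c(-1.5, 1.5),
                  ylim = c(-1.5, 1.5))
  rmb <- rate_map(pop, tr, bin_size = 0.125, xlim = c(-1.5, 1.5),
                  ylim = c(-1.5, 1.5))
  ca <- neftools:::rate_map_centroid(rma, 1)
  cb <- neftools:::rate_map_centroid(rmb, 1)
  expect_lt(max(abs(ca - cb)), 0.25)
  # spiking mode agrees with rate mode on the field location
  rms <- rate_map(pop, tr, bin_size = 0.25, xlim = c(-1.5, 1.5),
                  ylim = c(-1.5, 1.5), mode = "spiking")
  cs <- neftools:::rate_map_centroid(rms, 1)
  expect_lt(max(abs(cs - ca)), 0.3)
})
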