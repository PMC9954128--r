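test_that("encodings are real, unit norm, and phase-additive", {
  sp <- ssp_space(d = 101, m = 2, length_scale = 0.5, seed = 61)
  set.seed(61)
  for (i in 1:20) {
    x <- runif(2, -3, 3)
    v <- ssp_encode(sp, x)
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
    # imaginary part forced to zero by conjugate symmetry
    F <- exp(1i * as.numeric(sp$A %*% x))
    expect_lt(max(abs(Im(fft(F, inverse = TRUE) / sp$d))), 1e-12)
  }
  # phi(0) is the binding identity
  id <- ssp_encode(sp, c(0, 0))
  expect_equal(Mod(fft(id)), rep(1, 101), tolerance = 1e-12)
  a <- ssp_encode(sp, c(0.3, -0.7))
  expect_equal(ssp_bind(a, id), a, tolerance = 1e-12)
  expect_equal(sum(a * a), 1, tolerance = 1e-12)
})

test_that("binding is the encoding homomorphism and unbinding inverts it", {
  sp <- ssp_space(d = 101, m = 2, length_scale = 0.5, seed = 62)
  set.seed(62)
  for (i in 1:50) {
    x <- runif(2, -4, 4)
    y <- runif(2, -4, 4)
    expect_lt(max(abs(ssp_bind(ssp_encode(sp, x), ssp_encode(sp, y)) -
                        ssp_encode(sp, x + y))), 1e-10)
  }
  vocab <- make_vocabulary(c("U", "V"), 101, seed = 63)
  a <- ssp_encode(sp, c(1, 2))
  expect_lt(max(abs(ssp_unbind(ssp_bind(a, vocab$U), vocab$U) - a)), 1e-10)
  # commutative and associative
  b <- vocab$U; cvec <- vocab$V
  expect_lt(max(abs(ssp_bind(a, b) - ssp_bind(b, a))), 1e-10)
  expect_lt(max(abs(ssp_bind(ssp_bind(a, b), cvec) -
                      ssp_bind(a, ssp_bind(b, cvec)))), 1e-10)
})

test_that("the induced kernel is shift-invariant and sinc-like", {
  sp <- ssp_space(d = 301, m = 1, length_scale = 0.5, seed = 64)
  dx <- seq(-3, 3, 0.05)
  k <- sapply(dx, function(z) induced_kernel(sp, z, 0))
  sinc <- ifelse(dx == 0, 1, sin(pi * dx / 0.5) / (pi * dx / 0.5))
  expect_lt(max(abs(k - sinc)), 0.05)
  # shift invariance on translated pairs
  set.seed(64)
  for (i in 1:10) {
    x <- runif(1); s <- runif(1, -2, 2)
    expect_equal(induced_kernel(sp, x + s, s), induced_kernel(sp, x, 0),
                 tolerance = 1e-12)
  }
})

test_that("hex spaces show hexagonal interference and symmetry", {
  hx <- ssp_space(m = 2, kind = "hex", length_scale = 0.5, seed = 65)
  expect_equal(hx$d, 151)
  expect_equal(sqrt(sum(ssp_encode(hx, c(1, 2))^2)), 1, tolerance = 1e-12)
  rotv <- function(v, th) c(cos(th) * v[1] - sin(th) * v[2],
                            sin(th) * v[1] + cos(th) * v[2])
  set.seed(65)
  k0 <- k60 <- k30 <- numeric(30)
  for (i in 1:30) {
    v <- runif(2, -1.5, 1.5)
    k0[i] <- induced_kernel(hx, v, c(0, 0))
    k60[i] <- induced_kernel(hx, rotv(v, pi / 3), c(0, 0))
    k30[i] <- induced_kernel(hx, rotv(v, pi / 6), c(0, 0))
  }
  expect_lt(max(abs(k60 - k0)), 1e-10)     # 60-degree rotation: invariant
  expect_gt(max(abs(k30 - k0)), 0.05)      # 30-degree rotation: not
})

test_that("single-module similarity maps have hexagonal peaks", {
  hx <- ssp_space(m = 2, kind = "hex", length_scale = 0.5, seed = 66,
                  n_scales = 1, n_rotations = 1, scale_range = c(1, 1))
  g <- seq(-2.5, 2.5, 0.05)
  grid <- as.matrix(expand.grid(g, g))
  sims <- matrix(ssp_encode_many(hx, grid) %*% ssp_encode(hx, c(0, 0)),
                 length(g), length(g))
  pk <- neftools:::find_peaks(list(sim = sims, x = g, y = g), 0.9)
  # central peak surrounded by 6 first-ring peaks at equal radii
  r <- sqrt(rowSums(pk[, 1:2]^2))
  ring <- pk[r > 0.1 & r < 2 * min(r[r > 0.1]), , drop = FALSE]
  expect_gte(nrow(ring), 6)
  rr <- sqrt(rowSums(ring[, 1:2]^2))
  expect_lt(diff(range(rr)) / mean(rr), 0.15)
})

test_that("decoding inverts encoding and tolerates additive noise", {
  sp <- ssp_space(d = 129, m = 1, length_scale = 0.5, seed = 67)
  set.seed(67)
  for (i in 1:10) {
    x <- runif(1, -2, 2)
    est <- ssp_decode(sp, ssp_encode(sp, x), lower = -3, upper = 3)
    expect_lt(abs(est$x - x), 1e-3 * 0.5)
    expect_true(est$reliable)
  }
  # binding identity: decode(bind(phi(x), phi(y))) = x + y
  est <- ssp_decode(sp, ssp_bind(ssp_encode(sp, 0.8), ssp_encode(sp, -0.3)),
                    lower = -3, upper = 3)
  expect_lt(abs(est$x - 0.5), 1e-3)
  # Monte-Carlo under noise of norm 0.3
  errs <- sapply(1:20, function(i) {
    x <- runif(1, -2, 2)
    nz <- rnorm(129)
    nz <- nz / sqrt(sum(nz^2)) * 0.3
    abs(ssp_decode(sp, ssp_encode(sp, x) + nz, lower = -3, upper = 3)$x - x)
  })
  expect_lt(max(errs), 0.1 * 0.5)
  # far-off-manifold vectors are flagged
  expect_false(ssp_decode(sp, rnorm(129) * 0.01, lower = -3, upper = 3)$reliable)
})

test_that("region encodings integrate the point encodings", {
  sp <- ssp_space(d = 201, m = 2, length_scale = 0.5, seed = 68)
  sq <- rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2))
  # boundary cells make the quadrature first order: refining the grid
  # halves the distance to a fine reference
  ref <- encode_region(sp, sq, spacing = sp$length_scale / 32)
  e4 <- sqrt(sum((encode_region(sp, sq) - ref)^2))
  e8 <- sqrt(sum((encode_region(sp, sq, spacing = sp$length_scale / 8) -
                    ref)^2))
  e16 <- sqrt(sum((encode_region(sp, sq, spacing = sp$length_scale / 16) -
                     ref)^2))
  expect_lt(e8, 0.7 * e4)
  expect_lt(e16, 0.7 * e8)
  v <- encode_region(sp, sq)
  # interior similarity beats far-outside similarity
  inside <- mean(ssp_encode_many(sp, rbind(c(1.3, 1.5), c(1.7, 1.3),
                                           c(1.5, 1.7))) %*% v)
  outside <- mean(ssp_encode_many(sp, rbind(c(3.5, 1.5), c(1.5, 3.5),
                                            c(-0.5, 1.5))) %*% v)
  expect_gt(inside, outside + 0.1)
  expect_error(encode_region(sp, rbind(c(1, 1), c(1, 1), c(1, 1))))
})

test_that("environment maps answer location queries", {
  sp <- ssp_space(d = 401, m = 2, length_scale = 0.5, seed = 69)
  vocab <- make_vocabulary(c("R", "C", "W", "X"), 401, seed = 70)
  items <- list(
    list(concept = "R", location = c(1, 2)),
    list(concept = "C", location = rbind(c(-2, -1), c(3, -3))),
    list(concept = "W", region = rbind(c(4, -5), c(5, -5), c(5, 5),
                                       c(4, 5))))
  mp <- build_map(sp, vocab, items)
  # rebuild invariant: E is the sum of its terms
  E2 <- ssp_bind(vocab$R, ssp_encode(sp, c(1, 2))) +
    ssp_bind(vocab$C, ssp_encode(sp, c(-2, -1)) + ssp_encode(sp, c(3, -3))) +
    ssp_bind(vocab$W, encode_region(sp, items[[3]]$region))
  expect_lt(max(abs(mp$E - E2)), 1e-10)
  qr <- query_map(mp, "R", c(-5, 5), c(-5, 5), 101)
  pk <- which(qr$sim == max(qr$sim), arr.ind = TRUE)
  expect_lt(max(abs(c(qr$x[pk[1]], qr$y[pk[2]]) - c(1, 2))), 0.11)
  # cheese query: two peaks above half max, at the two cheese locations
  qc <- query_map(mp, "C", c(-5, 5), c(-5, 5), 101)
  peaks <- neftools:::find_peaks(qc, max(qc$sim) / 2)
  expect_equal(nrow(peaks), 2L)
  got <- peaks[order(peaks[, 1]), 1:2]
  expect_lt(max(abs(got - rbind(c(-2, -1), c(3, -3)))), 0.11)
  # unknown concept: peak stays below the half-max detection level
  qx <- query_map(mp, "X", c(-5, 5), c(-5, 5), 101)
  expect_lt(max(qx$sim), max(qr$sim) / 2)
  expect_error(build_map(sp, vocab,
                         list(list(concept = "nope", location = c(0, 0)))))
  # empty item list gives the zero vector
  expect_equal(build_map(sp, vocab, list())$E, numeric(401))
})
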