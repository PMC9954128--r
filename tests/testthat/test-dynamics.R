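test_that("ideal path integration advances phases exactly", {
  sp <- ssp_space(d = 49, m = 2, length_scale = 20, seed = 91)
  # zero velocity: constant SSP
  tr0 <- path_integrate_ideal(sp, c(5, -3), matrix(0, 100, 2), 1e-3)
  expect_lt(max(abs(sweep(tr0, 2, ssp_encode(sp, c(5, -3))))), 1e-12)
  # constant velocity: phi(x0 + v T) to machine precision
  v <- matrix(rep(c(3, -2), each = 1000), 1000, 2)
  tr <- path_integrate_ideal(sp, c(10, 5), v, 1e-3)
  expect_lt(max(abs(tr[1000, ] - ssp_encode(sp, c(13, 3)))), 1e-8)
  # arbitrary velocity: matches encoding of the integrated path to O(dt)
  set.seed(91)
  vr <- matrix(rnorm(2000, 0, 10), 1000, 2)
  trr <- path_integrate_ideal(sp, c(0, 0), vr, 1e-3)
  xT <- colSums(vr) * 1e-3
  expect_lt(max(abs(trr[1000, ] - ssp_encode(sp, xT))), 1e-8)
})

test_that("oscillator phasors stay unitary over a long run", {
  sp <- ssp_space(d = 25, m = 2, length_scale = 20, seed = 92)
  set.seed(92)
  v <- matrix(rnorm(2 * 60000, 0, 15), ncol = 2)   # 60 s at 1 ms
  ph <- path_integrate_ideal(sp, c(0, 0), v, 1e-3, return_ssp = FALSE)
  mags <- Mod(exp(1i * ph[60000, ]))
  expect_lt(max(abs(mags - 1)), 1e-6)
})

test_that("path integration is equivariant in the start position", {
  sp <- ssp_space(d = 49, m = 2, length_scale = 20, seed = 93)
  set.seed(93)
  v <- matrix(rnorm(600, 0, 10), 300, 2)
  a <- path_integrate_ideal(sp, c(7, -4), v, 1e-3)[300, ]
  b <- path_integrate_ideal(sp, c(0, 0), v, 1e-3)[300, ]
  expect_lt(max(abs(a - ssp_bind(b, ssp_encode(sp, c(7, -4))))), 1e-10)
})

test_that("space-time encoding factorizes into space and time bindings", {
  sp <- ssp_space(d = 61, m = 1, length_scale = 0.3, seed = 94)
  b <- time_phase_vector(61, 0.3, seed = 95)
  expect_equal(encode_spacetime(sp, b, 0.4, 0), ssp_encode(sp, 0.4),
               tolerance = 1e-12)
  phi_t <- neftools:::idft_real(exp(1i * b * 1.3))
  expect_lt(max(abs(encode_spacetime(sp, b, 0.4, 1.3) -
                      ssp_bind(ssp_encode(sp, 0.4), phi_t))), 1e-10)
  expect_equal(sum(encode_spacetime(sp, b, 0.4, 1.3)^2), 1,
               tolerance = 1e-12)
})

# helper: response to encoded sum-of-streams minus sum of responses, where
# "sum of streams" means summing the two input encodings at each step
temporal_integrate_sum <- function(sp, b, x1, x2, dt) {
  n <- nrow(x1)
  rot <- exp(1i * b * dt)
  P <- complex(sp$d)
  F1 <- exp(1i * (sp$A %*% t(x1)))
  F2 <- exp(1i * (sp$A %*% t(x2)))
  for (k in seq_len(n)) P <- P * rot + (F1[, k] + F2[, k]) * dt
  both <- neftools:::idft_real(P)
  both - temporal_integrate(sp, b, x1, dt)[n, ] -
    temporal_integrate(sp, b, x2, dt)[n, ]
}

test_that("temporal integration steps match brute-force quadrature", {
  sp <- ssp_space(d = 61, m = 1, length_scale = 0.3, seed = 96)
  b <- time_phase_vector(61, 0.3, seed = 97)
  dt <- 0.01
  n <- 150
  x <- matrix(sin(seq_len(n) * dt * 2))
  ti <- temporal_integrate(sp, b, x, dt)
  # direct quadrature of the memory integral at the final time
  t_end <- n * dt
  quad <- Reduce(`+`, lapply(seq_len(n), function(k)
    encode_spacetime(sp, b, x[k, ], t_end - k * dt) * dt))
  expect_lt(max(abs(ti[n, ] - quad)), 1e-10)
  # b = 0 reduces to a running sum of encodings
  ti0 <- temporal_integrate(sp, rep(0, 61), x, dt)
  expect_equal(ti0[n, ], colSums(ssp_encode_many(sp, x)) * dt,
               tolerance = 1e-12)
  # linearity in the input stream
  x2 <- matrix(cos(seq_len(n) * dt * 3))
  lhs <- temporal_integrate_sum(sp, b, x, x2, dt)
  expect_lt(max(abs(lhs)), 1e-10)
})

test_that("a constant input produces a flat similarity ridge over lags", {
  sp <- ssp_space(d = 101, m = 1, length_scale = 0.3, seed = 98)
  b <- time_phase_vector(101, 0.3, seed = 99)
  dt <- 1e-3
  n <- 1200
  x <- matrix(rep(0.5, n))
  Phi <- temporal_integrate(sp, b, x, dt)[n, ]
  lags <- seq(0.1, 1.0, 0.1)
  vals <- seq(-0.5, 1.5, 0.02)
  sm <- trajectory_similarity_map(sp, b, Phi, vals, lags)
  # the ridge is flat: peak height barely varies across lags, and the peak
  # value wanders only within the kernel main lobe around the constant
  peak <- apply(sm, 2, max)
  expect_lt(diff(range(peak)) / mean(peak), 0.05)
  ridge <- vals[apply(sm, 2, which.max)]
  expect_lt(max(abs(ridge - 0.5)), 0.35)
  expect_lt(abs(mean(ridge) - 0.5), 0.12)
  # empty memory: flat surface
  sm0 <- trajectory_similarity_map(sp, b, numeric(101), vals, lags)
  expect_equal(max(abs(sm0)), 0)
})

test_that("a ramp input produces a ridge of slope -1", {
  sp <- ssp_space(d = 101, m = 1, length_scale = 0.3, seed = 3)
  b <- time_phase_vector(101, 0.3, seed = 4)
  dt <- 1e-3
  n <- 1500
  x <- matrix(seq_len(n) * dt)
  Phi <- temporal_integrate(sp, b, x, dt)[n, ]
  vals <- seq(-0.2, 1.7, 0.02)
  lags <- seq(0.1, 1.2, 0.05)
  sm <- trajectory_similarity_map(sp, b, Phi, vals, lags)
  ridge <- vals[apply(sm, 2, which.max)]
  slope <- coef(lm(ridge ~ lags))[2]
  expect_equal(unname(slope), -1, tolerance = 0.1)
})

test_that("the spiking temporal integrator tracks the ideal memory", {
  sp <- ssp_space(d = 101, m = 1, length_scale = 0.3, seed = 3)
  b <- time_phase_vector(101, 0.3, seed = 4)
  dt <- 1e-3
  n <- 1500
  x <- matrix(seq_len(n) * dt)
  res <- neural_temporal_integrator(sp, b, x, dt, seed = 5)
  i <- 200:n
  expect_lt(nrmse(res$Phi[i, ], res$ideal[i, ]), 0.3)
  # the ridge structure survives the spiking realization
  vals <- seq(-0.2, 1.7, 0.02)
  lags <- seq(0.1, 1.2, 0.05)
  sm <- trajectory_similarity_map(sp, b, res$Phi[n, ], vals, lags)
  ridge <- vals[apply(sm, 2, which.max)]
  expect_equal(unname(coef(lm(ridge ~ lags))[2]), -1, tolerance = 0.15)
})

test_that("the spiking path integrator tracks a short random walk", {
  sp <- ssp_space(d = 25, m = 2, length_scale = 20, seed = 11)
  tr <- gen_trajectory_2d(duration = 6, dt = 0.02, seed = 12)
  dt <- 1e-3
  tt <- seq(dt, 6, dt)
  xs <- approx(tr$t, tr$x, tt, rule = 2)$y
  ys <- approx(tr$t, tr$y, tt, rule = 2)$y
  vel <- cbind(c(diff(xs), 0), c(diff(ys), 0)) / dt
  res <- path_integrate_neural(sp, c(xs[1], ys[1]), vel, dt,
                               n_per_osc = 300, seed = 13)
  truth <- cbind(approx(tt, xs, res$t_dec)$y, approx(tt, ys, res$t_dec)$y)
  err <- sqrt(rowSums((res$path - truth)^2))
  expect_lt(median(err), 15)
  expect_true(all(res$reliable))
  # stationary input: decoded position drifts < 10% of the arena diameter
  res0 <- path_integrate_neural(sp, c(20, -10), matrix(0, 6000, 2), dt,
                                n_per_osc = 300, seed = 14,
                                lower = c(-90, -90), upper = c(90, 90))
  d0 <- sqrt(rowSums(sweep(res0$path, 2, c(20, -10))^2))
  expect_lt(max(d0), 18)
})
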