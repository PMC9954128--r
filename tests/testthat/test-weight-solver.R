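test_that("training-signal sampling is reproducible and well spread", {
  s1 <- sample_training_signals(2, 100, "static", seed = 41)
  s2 <- sample_training_signals(2, 100, "static", seed = 41)
  expect_identical(s1, s2)
  expect_true(all(rowSums(s1^2) <= 1 + 1e-12))
  # max nearest-neighbour gap shrinks with N (1-D for a cheap check)
  gap <- function(N) {
    x <- sort(sample_training_signals(1, N, "static", seed = 7)[, 1])
    max(diff(c(-1, x, 1)))
  }
  expect_lt(gap(500), gap(50) / 2)
})

test_that("temporal training signals are band-limited", {
  sig <- sample_training_signals(1, 3, "temporal", duration = 4, dt = 1e-3,
                                 bandwidth = 5, seed = 42)
  for (s in sig)
    expect_gt(neftools:::spectral_energy_below(s[, 1], 1e-3, 5), 0.99)
})

test_that("identity decoders reach RMSE < 0.05 with 100 neurons", {
  pre <- population(100, 1, seed = 43)
  D <- solve_decoders(pre, NULL, N = 800)
  g <- seq(-1, 1, 0.01)
  est <- as.numeric(D %*% static_tuning(pre, matrix(g)))
  expect_lt(sqrt(mean((est - g)^2)), 0.05)
})

test_that("decoding error shrinks with population size", {
  set.seed(44)
  err <- sapply(c(50, 100, 200, 400), function(n) {
    pre <- population(n, 1)
    D <- solve_decoders(pre, NULL, N = 1000)
    g <- seq(-0.95, 0.95, 0.01)
    sqrt(mean((as.numeric(D %*% static_tuning(pre, matrix(g))) - g)^2))
  })
  fit <- coef(lm(log(err) ~ log(c(50, 100, 200, 400))))
  expect_lt(fit[2], -0.5)
})

test_that("solve_weights realizes f(x) = x^2 in the post currents", {
  pre <- population(100, 1, seed = 45)
  post <- population(80, 1, seed = 46)
  conn <- solve_weights(nef_connection(pre, post, f = function(x) x^2),
                        N = 600)
  # factored path reproduces the full weights exactly
  W2 <- (post$encoders * (post$gains / post$radius)) %*% conn$decoders
  expect_lt(max(abs(conn$weights - W2)), 1e-8)
  # realized post currents approximate the tuning-demanded currents
  g <- seq(-1, 1, 0.05)
  A <- t(static_tuning(pre, matrix(g)))
  Jt <- (g^2) %*% t(post$encoders * post$gains)
  expect_lt(sqrt(mean((A %*% t(conn$weights) - Jt)^2)) /
              sd(Jt), 0.1)
})

test_that("f = 0 yields near-zero weights and bias-only currents", {
  pre <- population(60, 1, seed = 47)
  post <- population(60, 1, seed = 48)
  conn <- solve_weights(nef_connection(pre, post, f = function(x) 0),
                        N = 400)
  A <- t(static_tuning(pre, matrix(seq(-1, 1, 0.1))))
  drive <- A %*% t(conn$weights)
  expect_lt(max(abs(drive)), 1)          # well below threshold scale
})

test_that("x1*x2 is decodable jointly but not from independent populations", {
  set.seed(49)
  joint <- population(200, 2)
  Dj <- solve_decoders(joint, function(x) x[1] * x[2], N = 1500)
  g <- as.matrix(expand.grid(seq(-0.7, 0.7, 0.1), seq(-0.7, 0.7, 0.1)))
  err_joint <- sqrt(mean((as.numeric(Dj %*% static_tuning(joint, g)) -
                            g[, 1] * g[, 2])^2))
  p1 <- population(100, 1)
  p2 <- population(100, 1)
  A <- cbind(t(static_tuning(p1, matrix(g[, 1]))),
             t(static_tuning(p2, matrix(g[, 2]))))
  D <- neftools:::ridge_solve(A, matrix(g[, 1] * g[, 2]), 0.1 * max(A))
  err_indep <- sqrt(mean((A %*% D - g[, 1] * g[, 2])^2))
  expect_lt(err_joint, 0.05)
  expect_gt(err_indep, 5 * err_joint)
})

test_that("ridge solution is a local optimum of the regularized loss", {
  set.seed(50)
  A <- matrix(runif(200 * 20, 0, 100), 200, 20)
  y <- matrix(rnorm(200), 200, 1)
  sigma <- 5
  D <- neftools:::ridge_solve(A, y, sigma)
  loss <- function(d) sum((A %*% d - y)^2) + nrow(A) * sigma^2 * sum(d^2)
  L0 <- loss(D)
  for (i in 1:20) {
    expect_gt(loss(D + rnorm(20, 0, 1e-4)), L0)
  }
})

test_that("synaptic filters have unit DC gain and vanish for t < 0", {
  for (kind in c("exponential", "alpha")) {
    f <- synaptic_filter(kind, 0.01)
    t <- seq(0, 0.5, 1e-4)
    expect_equal(sum(filter_kernel(f, t)) * 1e-4, 1, tolerance = 1e-2)
    expect_equal(filter_kernel(f, -0.01), 0)
    # steady state of a constant input is the input
    y <- neftools:::filter_signal(f, matrix(rep(2.5, 3000)), 1e-3)
    expect_equal(y[3000, 1], 2.5, tolerance = 1e-3)
  }
})

test_that("low-pass mapping produces (tau A + I, tau B)", {
  sys <- make_ldn(3, 0.4)
  tr <- map_lti_through_lowpass(sys, 0.1)
  expect_equal(tr$Ap, 0.1 * sys$A + diag(3))
  expect_equal(tr$Bp, 0.1 * sys$B)
  # integrator: A' = I, B' = tau B
  integ <- lti_system(matrix(0), matrix(1), 1)
  tri <- map_lti_through_lowpass(integ, 0.05)
  expect_equal(tri$Ap, diag(1))
  expect_equal(tri$Bp, matrix(0.05))
  # eigenvalue mapping lambda -> tau lambda + 1
  expect_equal(sort(Re(eigen(tr$Ap)$values)),
               sort(Re(0.1 * eigen(sys$A)$values + 1)), tolerance = 1e-10)
  expect_error(map_lti_through_lowpass(sys,
                                       filter = synaptic_filter("alpha",
                                                                0.1)))
})

test_that("a spiking harmonic oscillator holds amplitude", {
  osc <- lti_system(matrix(c(0, -2 * pi, 2 * pi, 0), 2, 2),
                    matrix(c(0, 0), 2, 1), 1)
  tr <- map_lti_through_lowpass(osc, 0.1)
  pop <- population(300, 2, intercepts = c(-0.95, 0.95), radius = 1.1,
                    seed = 51)
  Dx <- solve_decoders(pop, NULL, N = 1500)
  net <- network(1e-3)
  net <- add_ensemble(net, "o", pop)
  net <- add_link(net, "o", "o", decoders = Dx, transform = tr$Ap,
                  synapse = synaptic_filter("exponential", 0.1),
                  init = c(0.8, 0))
  net <- add_probe(net, "o", "decoded", decoders = Dx,
                   synapse = synaptic_filter("exponential", 0.02))
  res <- run_network(net, 3, seed = 52)
  amp <- sqrt(rowSums(res$o.decoded^2))
  # amplitude drift < 10% per simulated period (1 s)
  expect_gt(min(amp[c(1000, 2000, 3000)] / amp[c(1, 1000, 2000)]), 0.9)
  expect_lt(max(amp), 1.2)
})

test_that("temporal weight solve realizes LDN-derived tuning", {
  set.seed(53)
  q <- 3
  theta <- 0.3
  dt <- 2e-3
  ldn <- make_ldn(q, theta)
  lag <- seq(0, theta, dt)
  basis <- impulse_response(ldn, lag)              # L x q
  n <- 60
  C <- matrix(rnorm(n * q), n, q)
  kern <- C %*% t(basis)                           # n x L temporal encoders
  pop <- population(n, 1, max_rates = c(100, 200), intercepts = c(-0.9, 0.9),
                    seed = 53)
  pop <- set_temporal_encoders(pop, kern, dt = dt)
  sol <- solve_temporal_weights(pop, n_probes = 12, probe_duration = 1.2,
                                bandwidth = 4,
                                filter = synaptic_filter("exponential",
                                                         0.05))
  expect_lt(sol$residual, 0.5)
  # zero desired encoders lead to near-zero weights
  pop0 <- set_temporal_encoders(pop, kern * 0, dt = dt, normalize = FALSE)
  sol0 <- solve_temporal_weights(pop0, n_probes = 4, probe_duration = 0.9,
                                 bandwidth = 4)
  expect_lt(max(abs(sol0$W_rec)), 1e-6)
})
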