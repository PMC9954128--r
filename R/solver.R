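#' Sample training signals for weight solving
#'
#' Static mode draws points uniformly from the represented domain (the unit
#' ball of the pre-population scaled by its radius, or a hypercube).
#' Temporal mode draws band-limited noise signals.  Reproducible under
#' `seed`.
#'
#' @param dim domain dimensionality.
#' @param N number of samples / signals.
#' @param mode "static" or "temporal".
#' @param radius domain radius (static mode).
#' @param shape "ball" or "cube" sampling law for static mode.
#' @param duration,dt,bandwidth temporal-mode signal parameters.
#' @param seed optional seed.
#' @return static: N x dim matrix; temporal: list of T x dim matrices.
#' @export
sample_training_signals <- function(dim, N, mode = c("static", "temporal"),
                                    radius = 1, shape = c("ball", "cube"),
                                    duration = 2, dt = 1e-3, bandwidth = 5,
                                    seed = NULL) {
  mode <- match.arg(mode); shape <- match.arg(shape)
  stopifnot(N >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "static") {
    if (shape == "cube") {
      return(matrix(stats::runif(N * dim, -radius, radius), N, dim))
    }
    u <- random_unit_vectors(N, dim)
    r <- radius * stats::runif(N)^(1 / dim)
    return(u * r)
  }
  lapply(seq_len(N), function(k) {
    matrix(sapply(seq_len(dim), function(j)
      bandlimited_noise(duration, dt, bandwidth, rms = radius / 2)),
      ncol = dim)
  })
}

# Ridge regression: minimize |A x - y|^2 + N sigma^2 |x|^2 columnwise.
# A: N x n, y: N x m.  Returns n x m.  sigma is an absolute activity scale.
ridge_solve <- function(A, y, sigma) {
  n <- ncol(A)
  G <- crossprod(A) + nrow(A) * sigma^2 * diag(n)
  if (sigma == 0) {
    sv <- svd(crossprod(A))
    if (min(sv$d) < 1e-10 * max(sv$d)) {
      warning("rank-deficient system with zero regularization; ",
              "using pseudo-inverse")
      return(MASS_ginv(crossprod(A)) %*% crossprod(A, y))
    }
  }
  solve(G, crossprod(A, y))
}

# Moore-Penrose pseudo-inverse via SVD (small helper; avoids a MASS import
# for one corner case).
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}


# Evaluate a decoded-target function over rows of a sample matrix; returns
# an N x dim_out matrix whatever the function's output width.
eval_targets <- function(f, signals) {
  y <- apply(signals, 1, function(x) as.numeric(f(x)))
  if (is.matrix(y)) t(y) else matrix(y, ncol = 1)
}
#' Solve for decoders of a function from a population
#'
#' Least-squares (ridge) readout weights `D` such that `f(x) ~ D a(x)` over
#' training samples, with the regularization scaled to pre-population
#' activity (`sigma = reg * max rate`).
#'
#' @param pre a [population()].
#' @param f function of a domain point returning the decoded target (vector),
#'   or NULL for the identity.
#' @param signals N x dim matrix of training points; default drawn by
#'   [sample_training_signals()].
#' @param reg relative ridge parameter (default 0.1).
#' @param N training sample count if `signals` is NULL.
#' @return dim_out x n decoder matrix with attributes `residual` (RMS current
#'   residual proxy in decoded units) and `signals`.
#' @export
solve_decoders <- function(pre, f = NULL, signals = NULL, reg = 0.1,
                           N = 500 * pre$dim) {
  if (is.null(signals))
    signals <- sample_training_signals(pre$dim, N, "static",
                                       radius = pre$radius)
  A <- t(static_tuning(pre, signals))          # N x n activities
  y <- if (is.null(f)) signals else eval_targets(f, signals)
  sigma <- reg * max(A)
  D <- t(ridge_solve(A, y, sigma))             # dim_out x n
  attr(D, "residual") <- sqrt(mean((A %*% t(D) - y)^2))
  attr(D, "signals") <- signals
  D
}

#' Connection between two populations
#'
#' Describes a pre -> post link computing `y = f(x)` through a synaptic
#' filter.  Weights may be stored factored (decoders, with the post
#' population's gains/encoders completing the product) or full.
#'
#' @param pre,post [population()] objects.
#' @param f decoded function (NULL = identity).
#' @param filter a [synaptic_filter()].
#' @param reg relative ridge regularization.
#' @return object of class `nef_connection` (unsolved until
#'   [solve_weights()]).
#' @export
nef_connection <- function(pre, post, f = NULL,
                           filter = synaptic_filter("exponential", 0.005),
                           reg = 0.1) {
  structure(list(pre = pre, post = post, f = f, filter = filter, reg = reg,
                 weights = NULL, decoders = NULL),
            class = "nef_connection")
}

#' Solve for the synaptic weights of a connection
#'
#' Ridge-regularized least squares mapping filtered pre-synaptic activities
#' onto the currents demanded by the post-population tuning constraint at
#' `f(x)`.  For static tuning the steady-state filtered activity equals the
#' rate (unit DC gain), so the fit runs over sampled domain points; the
#' factored shortcut (`decoders`, then post gains and encoders) is also
#' stored and reproduces the full weights exactly.
#'
#' @param conn an [nef_connection()].
#' @param signals optional N x dim training points.
#' @param N sample count when `signals` is NULL.
#' @return the connection with `weights` (n_post x n_pre), `decoders` and
#'   `residual` fields filled in.
#' @export
solve_weights <- function(conn, signals = NULL, N = 500 * conn$pre$dim) {
  pre <- conn$pre; post <- conn$post
  if (is.null(signals))
    signals <- sample_training_signals(pre$dim, N, "static",
                                       radius = pre$radius)
  A <- t(static_tuning(pre, signals))            # N x n_pre
  y <- if (is.null(conn$f)) signals else eval_targets(conn$f, signals)
  stopifnot(ncol(y) == post$dim)
  # target currents J_i(f(x_k)) from the post tuning constraint
  Jt <- y %*% t(post$encoders * (post$gains / post$radius))   # N x n_post
  sigma <- conn$reg * max(A)
  # factored path: decode f(x), then encode into post currents
  D <- t(ridge_solve(A, y, sigma))               # dim x n_pre
  W <- (post$encoders * (post$gains / post$radius)) %*% D     # n_post x n_pre
  conn$decoders <- D
  conn$weights <- W
  pred <- A %*% t(W)
  conn$residual <- sqrt(mean((pred - Jt)^2))
  conn$signals <- signals
  conn
}

#' Map an LTI system through a first-order synapse
#'
#' A recurrently connected population whose synapses are exponential filters
#' with time constant `tau` realizes `x' = A x + B u` when the recurrent
#' transform is `A' = tau A + I` and the input transform is `B' = tau B`
#' (the low-pass is thereby compensated into a perfect integrator).
#'
#' @param sys an [lti_system()].
#' @param tau recurrent synapse time constant (s).
#' @param filter optional [synaptic_filter()]; must be exponential.
#' @return list(Ap, Bp) transform matrices.
#' @export
map_lti_through_lowpass <- function(sys, tau = 0.1, filter = NULL) {
  if (!is.null(filter)) {
    if (filter$kind != "exponential")
      stop("low-pass dynamics compensation requires an exponential synapse; ",
           "use solve_temporal_weights for other filters")
    tau <- filter$tau
  }
  list(Ap = tau * sys$A + diag(sys$q), Bp = tau * sys$B)
}

#' Solve recurrent weights for desired temporal tuning
#'
#' The general temporal weight solve: probe signals are run through the
#' desired temporal encoders to obtain target currents over time; the same
#' probes drive the (assumed-realized) desired activities, which are passed
#' through the synaptic filter; recurrent plus input weights are then the
#' ridge solution fitting filtered activities (and filtered input) to the
#' target currents on a uniform evaluation grid over the probes.
#'
#' @param pop population with temporal encoders (see
#'   [set_temporal_encoders()]).
#' @param probes list of probe input signals (vectors or T x dim matrices)
#'   sampled at the encoder lag spacing; default band-limited noise.
#' @param filter recurrent [synaptic_filter()].
#' @param n_probes,probe_duration,bandwidth probe generation parameters used
#'   when `probes` is NULL.
#' @param reg relative ridge parameter.
#' @param residual_warn warn if the relative current residual exceeds this.
#' @return list(W_rec n x n, W_in n x dim, residual) of class
#'   `temporal_solve`.
#' @export
solve_temporal_weights <- function(pop, probes = NULL,
                                   filter = synaptic_filter("exponential",
                                                            0.1),
                                   n_probes = 32, probe_duration = NULL,
                                   bandwidth = 5, reg = 0.1,
                                   residual_warn = 0.5) {
  tp <- pop$temporal
  if (is.null(tp)) stop("population must carry temporal encoders")
  dt <- tp$dt
  theta <- (tp$L - 1) * dt
  if (is.null(probe_duration)) probe_duration <- 4 * theta
  if (is.null(probes)) {
    probes <- lapply(seq_len(n_probes), function(k)
      matrix(sapply(seq_len(pop$dim), function(j)
        bandlimited_noise(probe_duration, dt, bandwidth)), ncol = pop$dim))
  }
  X <- NULL; Jt <- NULL; U <- NULL
  for (u in probes) {
    u <- matrix(u, ncol = pop$dim)
    Tn <- nrow(u)
    # desired currents at each time: lagged-history inner products with the
    # encoders, vectorized as one matrix product per stimulus dimension
    acc <- matrix(0, Tn, pop$n)
    for (j in seq_len(pop$dim)) {
      H <- stats::embed(c(rep(0, tp$L - 1), u[, j]), tp$L)   # Tn x L lags
      acc <- acc + H %*% (tp$weights * t(tp$kernels[, , j]))
    }
    Jmat <- sweep(acc * rep(pop$gains, each = Tn), 2, pop$biases, `+`)
    Amat <- lif_rate(Jmat, pop$neuron)             # desired activities
    Fa <- filter_signal(filter, Amat, dt)          # filtered activities
    Fu <- filter_signal(filter, u, dt)             # filtered input
    keep <- seq.int(tp$L, Tn)                      # past burn-in
    X <- rbind(X, cbind(Fa[keep, , drop = FALSE], Fu[keep, , drop = FALSE]))
    Jt <- rbind(Jt, Jmat[keep, , drop = FALSE])
  }
  target <- sweep(Jt, 2, pop$biases)               # weights supply J - beta
  sigma <- reg * max(X[, seq_len(pop$n)])
  Wall <- ridge_solve(X, target, sigma)            # (n + dim) x n
  W_rec <- t(Wall[seq_len(pop$n), , drop = FALSE])
  W_in <- t(Wall[pop$n + seq_len(pop$dim), , drop = FALSE])
  spread <- stats::sd(target)
  if (!is.finite(spread) || spread == 0) spread <- 1
  res <- sqrt(mean((X %*% Wall - target)^2)) / spread
  if (res > residual_warn)
    warning(sprintf("temporal solve residual %.2f exceeds %.2f", res,
                    residual_warn))
  structure(list(W_rec = W_rec, W_in = W_in, residual = res,
                 filter = filter, dt = dt), class = "temporal_solve")
}
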