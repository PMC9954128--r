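#' Run a packaged experiment end to end
#'
#' Desk-scale reproductions of the model zoo, each runnable from a fresh
#' session with no external data: synthetic fixtures are generated under the
#' configured seed, the model is built and simulated, and CSV traces plus a
#' JSON summary are written to `out_dir` (when given).  This is the engine
#' behind the command-line script in `inst/cli/neftools.R`.
#'
#' @param name one of "timecells", "pendulum", "llp-ball", "gridcells",
#'   "pathint", "trajectory-memory", "kde", "square".
#' @param config named list of overrides for the experiment's parameters
#'   (see each underlying function); `config$seed` defaults to 1.
#' @param out_dir output directory (created if missing), or NULL to skip
#'   writing files.
#' @return the experiment's summary list (invisibly when writing files).
#' @export
run_experiment <- function(name, config = list(), out_dir = NULL) {
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$seed <- NULL
  runner <- switch(name,
                   timecells = experiment_timecells,
                   pendulum = experiment_pendulum,
                   `llp-ball` = experiment_llp_ball,
                   gridcells = experiment_gridcells,
                   pathint = experiment_pathint,
                   `trajectory-memory` = experiment_trajectory_memory,
                   kde = experiment_kde,
                   square = experiment_square,
                   stop("unknown experiment: ", name))
  out <- runner(config, seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out$tables)) {
      utils::write.csv(out$tables[[nm]],
                       file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    meta <- c(out$summary,
              list(experiment = name, seed = seed,
                   package_version = as.character(
                     utils::packageVersion("neftools"))))
    jsonlite::write_json(meta, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out$summary))
  }
  out$summary
}

merge_config <- function(defaults, config) {
  defaults[names(config)] <- config
  defaults
}

experiment_timecells <- function(config, seed) {
  cfg <- merge_config(list(n = 200, q = 7, theta = 0.5), config)
  res <- run_time_cell_experiment(n = cfg$n, q = cfg$q, theta = cfg$theta,
                                  seed = seed)
  list(summary = list(spearman = res$spearman,
                      active_fraction = mean(res$active),
                      unimodal_fraction =
                        unimodal_fraction(res$activities, res$on_idx,
                                          res$active)),
       tables = list(activities = data.frame(t = res$t, res$activities)))
}

experiment_pendulum <- function(config, seed) {
  cfg <- merge_config(list(duration = 200), config)
  res <- do.call(run_pendulum_prediction,
                 c(cfg, list(seed = seed)))
  list(summary = list(nrmse_final = res$nrmse_final,
                      nrmse_trace = res$nrmse_trace),
       tables = list(prediction = data.frame(t = res$t, angle = res$angle,
                                             prediction = res$prediction)))
}

experiment_llp_ball <- function(config, seed) {
  cfg <- merge_config(list(context = "ldn", duration = 100), config)
  res <- run_ball_prediction(context = cfg$context,
                             duration = cfg$duration, seed = seed)
  list(summary = list(context = res$context,
                      rmse_first = res$rmse_first,
                      rmse_last = res$rmse_last),
       tables = list(rmse = data.frame(window = seq_along(res$rmse_windowed),
                                       rmse = res$rmse_windowed)))
}

experiment_gridcells <- function(config, seed) {
  cfg <- merge_config(list(n = 30, sparsity = 0.2, extent = 2.5,
                           duration = 240), config)
  space <- ssp_space(m = 2, kind = "hex", length_scale = 0.4, seed = seed,
                     scale_range = c(1, 2.5))
  pop <- grid_cell_population(space, cfg$n, sparsity = cfg$sparsity,
                              extent = cfg$extent, seed = seed + 1)
  tr <- gen_trajectory_2d(arena = list(kind = "rect",
                                       width = 2 * cfg$extent,
                                       height = 2 * cfg$extent),
                          duration = cfg$duration, dt = 0.05,
                          mean_speed = 1.5, smoothness = 0.5,
                          seed = seed + 2)
  rm1 <- rate_map(pop, tr, bin_size = 0.2,
                  xlim = c(-cfg$extent, cfg$extent),
                  ylim = c(-cfg$extent, cfg$extent))
  gs <- sapply(seq_len(cfg$n), function(j) gridness_score(rm1, j))
  list(summary = list(gridness = gs, positive_fraction = mean(gs > 0)),
       tables = list(trajectory = tr,
                     ratemap_cell1 = as.data.frame(rm1$rates[, , 1])))
}

experiment_pathint <- function(config, seed) {
  cfg <- merge_config(list(duration = 60, d = 49, length_scale = 20,
                           n_per_osc = 500), config)
  space <- ssp_space(d = cfg$d, m = 2, kind = "random",
                     length_scale = cfg$length_scale, seed = seed)
  tr <- gen_trajectory_2d(duration = cfg$duration, dt = 0.02,
                          seed = seed + 1)
  dt <- 1e-3
  tt <- seq(dt, cfg$duration, dt)
  xs <- stats::approx(tr$t, tr$x, tt, rule = 2)$y
  ys <- stats::approx(tr$t, tr$y, tt, rule = 2)$y
  vel <- cbind(c(diff(xs), 0), c(diff(ys), 0)) / dt
  res <- path_integrate_neural(space, c(xs[1], ys[1]), vel, dt,
                               n_per_osc = cfg$n_per_osc, seed = seed + 2)
  truth <- cbind(stats::approx(tt, xs, res$t_dec)$y,
                 stats::approx(tt, ys, res$t_dec)$y)
  err <- sqrt(rowSums((res$path - truth)^2))
  list(summary = list(median_error_cm = stats::median(err),
                      max_error_cm = max(err)),
       tables = list(decoded = data.frame(t = res$t_dec,
                                          x = res$path[, 1],
                                          y = res$path[, 2],
                                          x_true = truth[, 1],
                                          y_true = truth[, 2],
                                          error = err)))
}

experiment_trajectory_memory <- function(config, seed) {
  cfg <- merge_config(list(d = 101, duration = 1.5, length_scale = 0.3,
                           length_scale_t = 0.3, neural = TRUE), config)
  space <- ssp_space(d = cfg$d, m = 1, length_scale = cfg$length_scale,
                     seed = seed)
  b <- time_phase_vector(cfg$d, cfg$length_scale_t, seed = seed + 1)
  dt <- 1e-3
  n <- round(cfg$duration / dt)
  x <- matrix(seq_len(n) * dt)                 # ramp x(t) = t
  vals <- seq(-0.2, cfg$duration + 0.2, 0.02)
  lags <- seq(0.1, cfg$duration - 0.3, 0.05)
  if (cfg$neural) {
    res <- neural_temporal_integrator(space, b, x, dt, seed = seed + 2)
    Phi <- res$Phi[n, ]
    nr <- nrmse(res$Phi[200:n, ], res$ideal[200:n, ])
  } else {
    Phi <- temporal_integrate(space, b, x, dt)[n, ]
    nr <- 0
  }
  sm <- trajectory_similarity_map(space, b, Phi, vals, lags)
  ridge <- vals[apply(sm, 2, which.max)]
  slope <- unname(stats::coef(stats::lm(ridge ~ lags))[2])
  list(summary = list(ridge_slope = slope, nrmse_vs_ideal = nr),
       tables = list(similarity = data.frame(lag = rep(lags,
                                                       each = length(vals)),
                                             value = rep(vals,
                                                         length(lags)),
                                             sim = as.numeric(sm))))
}

experiment_kde <- function(config, seed) {
  cfg <- merge_config(list(d = 301, length_scale = 0.5, n = 200), config)
  set.seed(seed)
  space <- ssp_space(d = cfg$d, m = 1, length_scale = cfg$length_scale,
                     seed = seed)
  xs <- c(stats::rnorm(cfg$n / 2, -2, 0.5), stats::rnorm(cfg$n / 2, 2, 0.7))
  qd <- fit_quasi_density(space, xs)
  g <- seq(-5, 5, 0.02)
  dens <- evaluate_density(qd, g)
  truth <- 0.5 * stats::dnorm(g, -2, 0.5) + 0.5 * stats::dnorm(g, 2, 0.7)
  list(summary = list(xi = qd$xi,
                      integral = sum(dens) * 0.02,
                      iae = sum(abs(dens - truth)) * 0.02),
       tables = list(density = data.frame(x = g, density = dens,
                                          truth = truth)))
}

experiment_square <- function(config, seed) {
  cfg <- merge_config(list(n = 100, duration = 2), config)
  set.seed(seed)
  pre <- population(cfg$n, 1, seed = seed)
  post <- population(cfg$n, 1, seed = seed + 1)
  conn <- solve_weights(nef_connection(pre, post, f = function(x) x^2))
  dec_post <- solve_decoders(post)
  net <- network(1e-3)
  net <- add_node(net, "u", function(t) sin(2 * pi * t))
  net <- add_ensemble(net, "pre", pre)
  net <- add_ensemble(net, "post", post)
  net <- add_link(net, "u", "pre")
  net <- add_link(net, "pre", "post", decoders = conn$decoders)
  net <- add_probe(net, "post", "decoded", decoders = dec_post)
  res <- run_network(net, cfg$duration, seed = seed + 2)
  x <- sin(2 * pi * res$t)
  xf <- filter_signal(synaptic_filter("exponential", 0.005), matrix(x), 1e-3)
  truth <- filter_signal(synaptic_filter("exponential", 0.02),
                         filter_signal(synaptic_filter("exponential", 0.005),
                                       matrix(xf^2), 1e-3), 1e-3)
  i <- seq.int(300, nrow(truth))
  list(summary = list(nrmse = nrmse(res$post.decoded[i, 1], truth[i, 1]),
                      residual = conn$residual),
       tables = list(decoded = data.frame(t = res$t,
                                          decoded = res$post.decoded[, 1],
                                          target = truth[, 1])))
}
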