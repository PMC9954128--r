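#' Time-stepped spiking network simulator
#'
#' A network holds input nodes (functions of time), ensembles (spiking
#' [population()]s), links carrying synaptically filtered signals, and
#' probes.  Execution order per step is deterministic: inputs -> filters ->
#' currents -> neurons -> probes.  Spikes have amplitude `1/dt`, so filtered
#' spike trains estimate rates in Hz.
#'
#' @param dt simulation step (s).
#' @return object of class `nef_network`.
#' @export
network <- function(dt = 1e-3) {
  stopifnot(dt > 0)
  structure(list(dt = dt, nodes = list(), ensembles = list(), links = list(),
                 probes = list()), class = "nef_network")
}

#' Add an input node
#'
#' @param net a [network()].
#' @param name unique node name.
#' @param fn function(t) returning a length-`dim` vector, or a T x dim matrix
#'   of presampled values (one row per step, recycled if exhausted).
#' @param dim output dimensionality.
#' @return the network.
#' @export
add_node <- function(net, name, fn, dim = 1L) {
  stopifnot(!(name %in% names(net$nodes)))
  net$nodes[[name]] <- list(fn = fn, dim = dim)
  net
}

#' Add an ensemble (spiking population)
#'
#' @param net a [network()].
#' @param name unique ensemble name.
#' @param pop a [population()] with an LIF neuron model.
#' @return the network.
#' @export
add_ensemble <- function(net, name, pop) {
  stopifnot(!(name %in% names(net$ensembles)))
  net$ensembles[[name]] <- pop
  net
}

#' Connect nodes and ensembles
#'
#' Three link kinds: a *decoded* link applies `decoders` (or the identity for
#' node sources) to the source activity, filters it, applies `transform`, and
#' adds the result to the target ensemble's represented input; a *current*
#' link applies a full weight matrix to filtered source activity and adds it
#' to the target's input current; a link onto a node name records a decoded
#' output stream (usable as a probe target).
#'
#' @param net a [network()].
#' @param from,to node/ensemble names.
#' @param decoders dim_out x n_pre matrix for ensemble sources (NULL =
#'   identity for node sources).
#' @param weights full n_post x n_pre current weights (alternative to
#'   `decoders`).
#' @param transform matrix (or scalar) applied after filtering.
#' @param synapse a [synaptic_filter()] or NULL for an unfiltered pass.
#' @param init optional initial filter output (decoded/current space).
#' @return the network.
#' @export
add_link <- function(net, from, to, decoders = NULL, weights = NULL,
                     transform = 1,
                     synapse = synaptic_filter("exponential", 0.005),
                     init = NULL) {
  src_ens <- from %in% names(net$ensembles)
  if (!src_ens && !(from %in% names(net$nodes)))
    stop("unknown source: ", from)
  if (!(to %in% names(net$ensembles)) && !(to %in% names(net$nodes)))
    stop("unknown target: ", to)
  net$links[[length(net$links) + 1L]] <-
    list(from = from, to = to, src_ens = src_ens, decoders = decoders,
         weights = weights, transform = transform, synapse = synapse,
         init = init)
  net
}

#' Probe a signal
#'
#' @param net a [network()].
#' @param target ensemble or node name.
#' @param what "spikes" (raw indicator), "rates" (spikes filtered with
#'   `synapse`), "decoded" (decoders applied to filtered spikes), or "input"
#'   (node value).
#' @param decoders required for `what = "decoded"`.
#' @param synapse probe filter for rates/decoded.
#' @param name probe name (defaults to `target.what`).
#' @return the network.
#' @export
add_probe <- function(net, target, what = c("decoded", "rates", "spikes",
                                            "input"),
                      decoders = NULL,
                      synapse = synaptic_filter("exponential", 0.02),
                      name = NULL) {
  what <- match.arg(what)
  if (is.null(name)) name <- paste(target, what, sep = ".")
  net$probes[[name]] <- list(target = target, what = what,
                             decoders = decoders, synapse = synapse)
  net
}

#' Run a network
#'
#' Repeatedly steps the network for `duration` seconds.  All randomness is
#' drawn from the single seeded generator, so runs are reproducible.
#'
#' @param net a [network()].
#' @param duration simulated time (s).
#' @param seed optional integer seed.
#' @return list with `t` (step times) and one T x dim matrix (or T x n) per
#'   probe.
#' @export
run_network <- function(net, duration, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- net$dt
  n_steps <- round(duration / dt)
  state <- network_init(net)
  out <- lapply(net$probes, function(p) NULL)
  times <- (seq_len(n_steps)) * dt
  # preallocate probe storage
  for (nm in names(net$probes)) {
    p <- net$probes[[nm]]
    width <- probe_width(net, p)
    out[[nm]] <- matrix(NA_real_, n_steps, width)
  }
  for (k in seq_len(n_steps)) {
    state <- network_step(net, state, times[k])
    for (nm in names(net$probes))
      out[[nm]][k, ] <- state$probe_vals[[nm]]
  }
  c(list(t = times), out)
}

probe_width <- function(net, p) {
  if (p$what == "input") return(net$nodes[[p$target]]$dim)
  pop <- net$ensembles[[p$target]]
  switch(p$what,
         spikes = pop$n, rates = pop$n,
         decoded = nrow(p$decoders))
}

network_init <- function(net) {
  ens <- lapply(net$ensembles, function(pop)
    list(state = lif_state(pop$n), spikes = numeric(pop$n)))
  links <- lapply(net$links, function(lk) {
    width <- link_width(net, lk)
    filter_state(if (is.null(lk$synapse))
      synaptic_filter("exponential", 1) else lk$synapse, width,
      value = lk$init)
  })
  probes <- lapply(net$probes, function(p)
    filter_state(p$synapse, probe_width(net, p)))
  list(ens = ens, links = links, probes = probes, probe_vals = list(),
       step = 0L)
}

link_width <- function(net, lk) {
  if (!lk$src_ens) return(net$nodes[[lk$from]]$dim)
  if (!is.null(lk$weights)) return(nrow(lk$weights))
  if (!is.null(lk$decoders)) return(nrow(lk$decoders))
  stop("ensemble-source link needs decoders or weights")
}

node_value <- function(node, t, k) {
  if (is.function(node$fn)) as.numeric(node$fn(t))
  else as.numeric(node$fn[min(k, nrow(node$fn)), ])
}

# One deterministic step at absolute time t.
network_step <- function(net, state, t) {
  dt <- net$dt
  k <- state$step + 1L
  node_vals <- lapply(net$nodes, node_value, t = t, k = k)
  # accumulate represented inputs and extra currents per ensemble
  xin <- lapply(net$ensembles, function(pop) numeric(pop$dim))
  jex <- lapply(net$ensembles, function(pop) numeric(pop$n))
  node_in <- lapply(net$nodes, function(nd) numeric(nd$dim))
  for (i in seq_along(net$links)) {
    lk <- net$links[[i]]
    src <- if (lk$src_ens) state$ens[[lk$from]]$spikes
    else node_vals[[lk$from]]
    raw <- if (!is.null(lk$weights)) as.numeric(lk$weights %*% src)
    else if (!is.null(lk$decoders)) as.numeric(lk$decoders %*% src)
    else src
    if (!is.null(lk$synapse)) {
      state$links[[i]] <- filter_step(lk$synapse, state$links[[i]], raw, dt)
      val <- state$links[[i]]$y
    } else val <- raw
    val <- if (is.matrix(lk$transform)) as.numeric(lk$transform %*% val)
    else lk$transform * val
    if (lk$to %in% names(net$ensembles)) {
      if (!is.null(lk$weights)) jex[[lk$to]] <- jex[[lk$to]] + val
      else xin[[lk$to]] <- xin[[lk$to]] + val
    } else {
      node_in[[lk$to]] <- node_in[[lk$to]] + val
    }
  }
  # neuron updates
  for (nm in names(net$ensembles)) {
    pop <- net$ensembles[[nm]]
    J <- pop$gains * as.numeric(pop$encoders %*% (xin[[nm]] / pop$radius)) +
      pop$biases + jex[[nm]]
    if (anyNA(J))
      stop("NaN current in ensemble ", nm, " at t = ", t)
    st <- lif_spike_step(state$ens[[nm]]$state, J, dt, pop$neuron)
    state$ens[[nm]]$state <- st$state
    state$ens[[nm]]$spikes <- st$spikes / dt
  }
  # probes
  pv <- list()
  for (nm in names(net$probes)) {
    p <- net$probes[[nm]]
    if (p$what == "input") {
      pv[[nm]] <- node_vals[[p$target]] + node_in[[p$target]]
      next
    }
    spikes <- state$ens[[p$target]]$spikes
    if (p$what == "spikes") {
      pv[[nm]] <- spikes * dt            # back to 0/1 indicators
    } else {
      raw <- if (p$what == "decoded") as.numeric(p$decoders %*% spikes)
      else spikes
      state$probes[[nm]] <- filter_step(p$synapse, state$probes[[nm]], raw,
                                        dt)
      pv[[nm]] <- state$probes[[nm]]$y
    }
  }
  state$probe_vals <- pv
  state$step <- k
  state
}
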