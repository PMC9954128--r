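#' Serialize model objects to JSON
#'
#' Round-trippable JSON representations of populations, LTI systems and SSP
#' spaces, for reproducibility and external tooling.  Arrays are written in
#' full precision.
#'
#' @param x a [population()], [lti_system()] or [ssp_space()].
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_model_json <- function(x, path) {
  obj <- if (inherits(x, "population")) {
    list(class = "population", n = x$n, dim = x$dim,
         encoders = x$encoders, gains = x$gains, biases = x$biases,
         max_rates = x$max_rates, intercepts = x$intercepts,
         radius = x$radius, neuron = unclass(x$neuron))
  } else if (inherits(x, "lti_system")) {
    list(class = "lti_system", A = x$A, B = x$B, theta = x$theta,
         label = x$label)
  } else if (inherits(x, "ssp_space")) {
    list(class = "ssp_space", A = x$A, d = x$d, m = x$m, kind = x$kind,
         length_scale = x$length_scale, modules = x$modules)
  } else stop("unsupported object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a serialized model object
#'
#' @param path file written by [write_model_json()].
#' @return the reconstructed object.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$class,
         population = {
           neuron <- if (obj$neuron$type == "lif")
             lif_params(obj$neuron$tau_rc, obj$neuron$tau_ref)
           else if (obj$neuron$type == "relu") relu_params(obj$neuron$slope)
           else sigmoid_params(obj$neuron$max_rate, obj$neuron$gain)
           pop <- population(obj$n, obj$dim, encoders = obj$encoders,
                             max_rates = obj$max_rates,
                             intercepts = obj$intercepts, neuron = neuron,
                             radius = obj$radius)
           pop$gains <- obj$gains
           pop$biases <- obj$biases
           pop
         },
         lti_system = lti_system(obj$A, obj$B, obj$theta, obj$label),
         ssp_space = {
           sp <- structure(list(A = obj$A, d = obj$d, m = obj$m,
                                kind = obj$kind,
                                length_scale = obj$length_scale,
                                free = 1 + seq_len((obj$d - 1) / 2),
                                modules = obj$modules),
                           class = "ssp_space")
           sp
         },
         stop("unknown class in file"))
}
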