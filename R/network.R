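# Network specification: an ordered, strictly sequential chain of layers.

#' Create a sequential network specification
#'
#' Networks are strictly sequential chains: layer i consumes exactly the output
#' of layer i-1, with no branching or skip connections. This is the class of
#' architectures on which per-layer prediction/error nodes are well defined.
#'
#' @param layers List of [layer_affine()] / [layer_conv_block()] descriptions.
#' @param input_dim Width of the (flattened) input presented to layer 1.
#' @return A `pcnet_spec` object.
#' @export
network_spec <- function(layers, input_dim) {
  stopifnot(length(layers) >= 1)
  input_dim <- as.integer(input_dim)
  d <- input_dim
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (!inherits(l, "pcnet_layer")) stop("layer ", i, " is not a pcnet_layer")
    if (l$d_in != d)
      stop("layer ", i, " expects input width ", l$d_in, " but receives ", d)
    d <- l$d_out
  }
  structure(list(layers = layers, input_dim = input_dim, output_dim = d,
                 n_layers = length(layers)),
            class = "pcnet_spec")
}

#' @export
print.pcnet_spec <- function(x, ...) {
  cat("pcnet network spec: ", x$n_layers, " layers, input ", x$input_dim,
      " -> output ", x$output_dim, "\n", sep = "")
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    extra <- if (l$kind == "conv_block")
      paste0(" [", paste(l$in_shape, collapse = "x"), " -> ",
             paste(l$out_shape, collapse = "x"),
             if (l$has_batchnorm) ", bn" else "", "]") else ""
    cat(sprintf("  %d: %s %d -> %d (%s%s)%s\n", i, l$kind, l$d_in, l$d_out,
                l$nonlinearity,
                if (l$dropout_rate > 0) paste0(", dropout ", l$dropout_rate) else "",
                extra))
  }
  invisible(x)
}

#' Initialize network parameters
#'
#' Scaled uniform fan-in initialization, `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`,
#' for weights and biases; batch-norm scale/shift start at 1/0.
#'
#' @param spec A `pcnet_spec`.
#' @param seed Integer seed; every stochastic entry point takes one explicitly.
#' @return A list of per-layer parameter lists (class `pcnet_params`).
#' @export
init_params <- function(spec, seed = 1L) {
  set.seed(seed)
  structure(lapply(spec$layers, layer_init), class = "pcnet_params")
}

#' Count trainable parameters
#' @param params A `pcnet_params` list.
#' @return Integer total number of scalar parameters.
#' @export
n_params <- function(params) length(unlist(params, use.names = FALSE))

#' Serialize a network spec to JSON
#'
#' Writes a human-readable description (layer kinds, shapes, nonlinearities,
#' dropout, batch-norm flags) that [spec_from_json()] reconstructs exactly,
#' including the precomputed index tables.
#'
#' @param spec A `pcnet_spec`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
spec_to_json <- function(spec, path = NULL) {
  ls <- lapply(spec$layers, function(l) {
    if (l$kind == "affine")
      list(kind = "affine", d_in = l$d_in, d_out = l$d_out,
           nonlinearity = l$nonlinearity, dropout_rate = l$dropout_rate)
    else
      list(kind = "conv_block", in_shape = l$in_shape, out_channels = l$out_channels,
           kernel = l$kernel, pad = l$pad, pool = l$pool,
           batchnorm = l$has_batchnorm, nonlinearity = l$nonlinearity,
           dropout_rate = l$dropout_rate)
  })
  js <- jsonlite::toJSON(list(input_dim = spec$input_dim, layers = ls),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Reconstruct a network spec from JSON
#' @param x A JSON string or file path written by [spec_to_json()].
#' @return A `pcnet_spec`.
#' @export
spec_from_json <- function(x) {
  o <- jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  layers <- lapply(o$layers, function(l) {
    if (l$kind == "affine")
      layer_affine(l$d_in, l$d_out, l$nonlinearity, l$dropout_rate)
    else
      layer_conv_block(unlist(l$in_shape), l$out_channels, l$kernel, l$pad,
                       l$pool, l$batchnorm, l$nonlinearity, l$dropout_rate)
  })
  network_spec(layers, o$input_dim)
}

#' Save / load a parameter checkpoint
#'
#' Round-trips bit-exactly through R's native serialization.
#' @param params A `pcnet_params` list.
#' @param path File path.
#' @export
save_checkpoint <- function(params, path) { saveRDS(params, path); invisible(path) }

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
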