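# Network constructors for the three experiment families.

#' Three-layer multilayer perceptron
#'
#' Two ReLU hidden layers of `hidden_width` units (default 800) and a linear
#' classifier head; optional dropout on the hidden layers for the long-tailed
#' configuration.
#'
#' @param input_dim Flattened input width (e.g. 784 for 28x28 images).
#' @param hidden_width Hidden layer width (default 800).
#' @param classes Number of output classes.
#' @param dropout_rate Dropout on hidden layers (default 0; the long-tailed
#'   runs use 0.5).
#' @return A `pcnet_spec` with layer output widths
#'   `(hidden_width, hidden_width, classes)`.
#' @export
make_mlp3 <- function(input_dim, hidden_width = 800, classes, dropout_rate = 0) {
  if (input_dim < 1 || hidden_width < 1 || classes < 1)
    stop("make_mlp3: dimensions must be positive")
  network_spec(list(
    layer_affine(input_dim, hidden_width, "relu", dropout_rate),
    layer_affine(hidden_width, hidden_width, "relu", dropout_rate),
    layer_affine(hidden_width, classes, "identity")
  ), input_dim)
}

#' Simplified three-block convolutional network
#'
#' Three convolutional blocks with 64, 128, and 256 channels (3x3 kernels,
#' stride 1, same padding, ReLU, 2x2 max pooling — each block one predictive
#' coding layer), followed by a single affine classifier head. Kernel and pool
#' sizes are configurable; the channel plan is fixed.
#'
#' @param input_shape Integer `c(H, W, C)` image shape (e.g. `c(32, 32, 3)`).
#' @param classes Number of output classes.
#' @param kernel,pool Convolution kernel and pooling window (defaults 3 and 2).
#' @param batchnorm Use batch normalization inside the blocks (default FALSE).
#' @return A `pcnet_spec`.
#' @export
make_alexnet3 <- function(input_shape, classes, kernel = 3, pool = 2, batchnorm = FALSE) {
  stopifnot(length(input_shape) == 3, classes >= 1)
  channels <- c(64L, 128L, 256L)
  shape <- as.integer(input_shape)
  layers <- list()
  for (ch in channels) {
    l <- layer_conv_block(shape, ch, kernel = kernel, pool = pool, batchnorm = batchnorm)
    layers[[length(layers) + 1L]] <- l
    shape <- l$out_shape
  }
  layers[[length(layers) + 1L]] <-
    layer_affine(prod(shape), classes, "identity")
  network_spec(layers, prod(as.integer(input_shape)))
}

#' Four-block prototypical-network encoder
#'
#' Four identical convolutional blocks (64 channels, 3x3 kernels, batch
#' normalization, ReLU, 2x2 max pooling), each one predictive coding layer,
#' flattening to an embedding with no classifier head. With 28x28x1 input the
#' embedding dimension is 64 after the four poolings.
#'
#' @param input_shape Integer `c(H, W, C)` image shape.
#' @param channels Channels per block (default 64).
#' @return A `pcnet_spec` whose output is the embedding.
#' @export
make_protonet4 <- function(input_shape, channels = 64) {
  stopifnot(length(input_shape) == 3)
  shape <- as.integer(input_shape)
  layers <- list()
  for (b in 1:4) {
    l <- layer_conv_block(shape, channels, kernel = 3, pool = 2, batchnorm = TRUE)
    layers[[length(layers) + 1L]] <- l
    shape <- l$out_shape
  }
  network_spec(layers, prod(as.integer(input_shape)))
}
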