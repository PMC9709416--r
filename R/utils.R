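#' @keywords internal
"_PACKAGE"

# Numerically stable row-wise softmax.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' One-hot encode integer labels
#'
#' @param y Integer labels in 1..n_classes.
#' @param n_classes Number of classes.
#' @return An n x n_classes 0/1 matrix.
#' @export
one_hot <- function(y, n_classes) {
  n <- length(y)
  m <- matrix(0, n, n_classes)
  m[cbind(seq_len(n), y)] <- 1
  m
}

# Max relative elementwise error between two parameter sets / gradient sets,
# scaled by the largest magnitude in the reference.
max_rel_err <- function(a, b) {
  av <- unlist(a, use.names = FALSE)
  bv <- unlist(b, use.names = FALSE)
  stopifnot(length(av) == length(bv))
  scale <- max(abs(bv), 1e-12)
  max(abs(av - bv)) / scale
}

# Deterministic derived seed, kept well below 2^31.
derive_seed <- function(seed, i) {
  ((as.numeric(seed) %% 100003) * 8191 + as.numeric(i) * 7919 + 13) %% 2147483629
}

#' Round half away from zero
#'
#' The reporting convention for accuracy tables (base `round()` is
#' round-half-even, which would turn 86.395 into 86.39).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent accuracy of predicted versus true labels
#' @param pred,truth Equal-length label vectors.
#' @return Accuracy in percent.
#' @export
accuracy_pct <- function(pred, truth) 100 * mean(pred == truth)

# Split indices into minibatches after a seeded shuffle.
minibatch_indices <- function(n, batch_size) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
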