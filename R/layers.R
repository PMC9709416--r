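# Layer primitives for strictly sequential predictive coding networks.
#
# Every layer kind implements three operations on frozen forward context:
#   layer_forward(layer, params, x, training, frozen) -> list(out, ctx)
#   layer_jtv(layer, params, ctx, e_out)              -> Jacobian-transpose product
#   layer_pgrad(layer, params, ctx, e_out)            -> d(e . vhat)/d(theta) / n
# Activations are n x d matrices; image maps use the natural (H, W, C) column-major
# vector layout per sample.

#' Affine layer specification
#'
#' A dense layer `f(x) = act(x W + b)` with optional inverted dropout applied to
#' the activation. The nonlinearity and dropout live inside the layer transform,
#' so the layer owns a single prediction/error node at its output.
#'
#' @param d_in,d_out Positive integer input/output widths.
#' @param nonlinearity `"relu"` or `"identity"`. The ReLU derivative at 0 is 0.
#' @param dropout_rate Dropout probability in `[0, 1)`; masks are drawn once per
#'   minibatch in the forward phase and frozen during inference.
#' @return A `pcnet_layer` description (no parameters attached).
#' @export
layer_affine <- function(d_in, d_out, nonlinearity = "relu", dropout_rate = 0) {
  stopifnot(d_in >= 1, d_out >= 1, dropout_rate >= 0, dropout_rate < 1)
  nonlinearity <- match.arg(nonlinearity, c("relu", "identity"))
  structure(list(kind = "affine", d_in = as.integer(d_in), d_out = as.integer(d_out),
                 nonlinearity = nonlinearity, dropout_rate = dropout_rate,
                 has_batchnorm = FALSE),
            class = "pcnet_layer")
}

#' Convolutional block layer specification
#'
#' One predictive coding layer comprising convolution (3x3 by default, stride 1,
#' zero padding), optional batch normalization, nonlinearity, and 2x2 max
#' pooling (floor division on odd spatial sizes). The whole block owns a single
#' error node at its pooled output, following the block-unit convention for
#' composite layers.
#'
#' @param in_shape Integer vector `c(H, W, C)` of the input feature map.
#' @param out_channels Number of convolution filters.
#' @param kernel Odd kernel size (default 3).
#' @param pad Zero padding (default `(kernel-1)/2`, i.e. "same" convolution).
#' @param pool Max-pool window/stride (default 2; 1 disables pooling).
#' @param batchnorm Apply per-channel batch normalization after the convolution.
#' @param nonlinearity,dropout_rate As in [layer_affine()].
#' @return A `pcnet_layer` description.
#' @export
layer_conv_block <- function(in_shape, out_channels, kernel = 3, pad = (kernel - 1) / 2,
                             pool = 2, batchnorm = TRUE, nonlinearity = "relu",
                             dropout_rate = 0) {
  stopifnot(length(in_shape) == 3, all(in_shape >= 1), out_channels >= 1,
            kernel >= 1, pad >= 0, pool >= 1, dropout_rate >= 0, dropout_rate < 1)
  H <- as.integer(in_shape[1]); W <- as.integer(in_shape[2]); C <- as.integer(in_shape[3])
  Hc <- H + 2L * pad - kernel + 1L
  Wc <- W + 2L * pad - kernel + 1L
  if (Hc < 1 || Wc < 1)
    stop("conv_block: spatial size ", H, "x", W, " too small for kernel ", kernel)
  Hp2 <- Hc %/% pool; Wp2 <- Wc %/% pool
  if (Hp2 < 1 || Wp2 < 1)
    stop("conv_block: conv output ", Hc, "x", Wc, " too small for pool ", pool)
  l <- list(kind = "conv_block", in_shape = c(H, W, C), out_channels = as.integer(out_channels),
            kernel = as.integer(kernel), pad = as.integer(pad), pool = as.integer(pool),
            has_batchnorm = isTRUE(batchnorm),
            nonlinearity = match.arg(nonlinearity, c("relu", "identity")),
            dropout_rate = dropout_rate,
            d_in = H * W * C, d_out = Hp2 * Wp2 * out_channels,
            conv_shape = c(Hc, Wc), out_shape = c(Hp2, Wp2, as.integer(out_channels)),
            bn_eps = 1e-5)
  l$idx <- conv_block_indices(l)
  structure(l, class = "pcnet_layer")
}

# Precompute gather/scatter linear index tables for a conv block.
conv_block_indices <- function(l) {
  H <- l$in_shape[1]; W <- l$in_shape[2]; C <- l$in_shape[3]
  k <- l$kernel; pad <- l$pad
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Hc <- l$conv_shape[1]; Wc <- l$conv_shape[2]
  # interior of the padded map (where real pixels live)
  hh <- rep(seq_len(H) + pad, times = W * C)
  ww <- rep(rep(seq_len(W) + pad, each = H), times = C)
  cc <- rep(seq_len(C), each = H * W)
  interior <- hh + Hp * (ww - 1L) + Hp * Wp * (cc - 1L)
  # im2col: rows ordered (dr, dw, c), columns ordered (oh, ow)
  P <- Hc * Wc
  kkC <- k * k * C
  oh <- rep(seq_len(Hc), times = Wc)
  ow <- rep(seq_len(Wc), each = Hc)
  dr <- rep(seq_len(k), times = k * C)
  dw <- rep(rep(seq_len(k), each = k), times = C)
  dc <- rep(seq_len(C), each = k * k)
  colidx <- matrix(0L, kkC, P)
  for (j in seq_len(kkC)) {
    h <- oh + dr[j] - 1L
    w <- ow + dw[j] - 1L
    colidx[j, ] <- h + Hp * (w - 1L) + Hp * Wp * (dc[j] - 1L)
  }
  # pooling: 4 (pool^2) candidate columns in the (Hc, Wc, OC) layout per output cell
  p <- l$pool; OC <- l$out_channels
  Hp2 <- Hc %/% p; Wp2 <- Wc %/% p
  P2 <- Hp2 * Wp2
  o2h <- rep(seq_len(Hp2), times = Wp2 * OC)
  o2w <- rep(rep(seq_len(Wp2), each = Hp2), times = OC)
  o2c <- rep(seq_len(OC), each = P2)
  poolidx <- matrix(0L, p * p, P2 * OC)
  jj <- 0L
  for (dcw in seq_len(p)) for (dch in seq_len(p)) {
    jj <- jj + 1L
    h <- (o2h - 1L) * p + dch
    w <- (o2w - 1L) * p + dcw
    poolidx[jj, ] <- h + Hc * (w - 1L) + Hc * Wc * (o2c - 1L)
  }
  list(interior = interior, colidx = colidx, poolidx = poolidx,
       Hp = Hp, Wp = Wp, P = P, P2 = P2, kkC = kkC)
}

relu <- function(z) { z[z < 0] <- 0; z }

# ---- affine ----------------------------------------------------------------

affine_forward <- function(layer, params, x, training, frozen) {
  n <- nrow(x)
  z <- x %*% params$W + rep(params$b, each = n)
  mask <- NULL
  if (layer$nonlinearity == "relu") {
    mask <- z > 0
    z <- z * mask
  }
  dmask <- NULL
  if (layer$dropout_rate > 0 && (training || !is.null(frozen))) {
    dmask <- if (!is.null(frozen)) frozen$dmask else
      matrix(stats::runif(n * layer$d_out) >= layer$dropout_rate, n, layer$d_out) /
        (1 - layer$dropout_rate)
    if (!is.null(dmask)) z <- z * dmask
  }
  list(out = z, ctx = list(x = x, mask = mask, dmask = dmask))
}

affine_delta <- function(layer, ctx, e_out) {
  d <- e_out
  if (!is.null(ctx$dmask)) d <- d * ctx$dmask
  if (!is.null(ctx$mask)) d <- d * ctx$mask
  d
}

affine_jtv <- function(layer, params, ctx, e_out) {
  affine_delta(layer, ctx, e_out) %*% t(params$W)
}

affine_pgrad <- function(layer, params, ctx, e_out) {
  n <- nrow(e_out)
  d <- affine_delta(layer, ctx, e_out)
  list(W = crossprod(ctx$x, d) / n, b = colSums(d) / n)
}

# ---- conv block ------------------------------------------------------------

conv_forward <- function(layer, params, x, training, frozen) {
  n <- nrow(x)
  ix <- layer$idx
  xpad <- matrix(0, n, ix$Hp * ix$Wp * layer$in_shape[3])
  xpad[, ix$interior] <- x
  m <- xpad[, as.vector(ix$colidx), drop = FALSE]
  dim(m) <- c(n, ix$kkC, ix$P)
  patches <- matrix(aperm(m, c(1L, 3L, 2L)), n * ix$P, ix$kkC)
  z <- patches %*% params$W + rep(params$b, each = n * ix$P)  # (n*P) x OC
  bn <- NULL
  if (layer$has_batchnorm) {
    if (!is.null(frozen)) {
      mu <- frozen$bn$mu; vr <- frozen$bn$vr
    } else {
      mu <- colMeans(z)
      vr <- colMeans(sweep(z, 2L, mu)^2)
    }
    scale <- 1 / sqrt(vr + layer$bn_eps)
    xhat <- sweep(sweep(z, 2L, mu), 2L, scale, `*`)
    z <- sweep(sweep(xhat, 2L, params$gamma, `*`), 2L, params$beta, `+`)
    bn <- list(mu = mu, vr = vr, scale = scale, xhat = xhat)
  }
  mask <- NULL
  if (layer$nonlinearity == "relu") {
    mask <- z > 0
    z <- z * mask
  }
  # to n x (P*OC) layout, then pool
  y <- matrix(as.vector(z), n, ix$P * layer$out_channels)
  amax <- NULL
  if (layer$pool > 1) {
    np <- nrow(ix$poolidx)
    best <- y[, ix$poolidx[1L, ], drop = FALSE]
    amax <- matrix(1L, n, ncol(best))
    for (j in 2:np) {
      cand <- y[, ix$poolidx[j, ], drop = FALSE]
      sel <- cand > best
      best[sel] <- cand[sel]
      amax[sel] <- j
    }
    y <- best
  }
  dmask <- NULL
  if (layer$dropout_rate > 0 && (training || !is.null(frozen))) {
    dmask <- if (!is.null(frozen)) frozen$dmask else
      matrix(stats::runif(length(y)) >= layer$dropout_rate, n, ncol(y)) /
        (1 - layer$dropout_rate)
    y <- y * dmask
  }
  list(out = y,
       ctx = list(patches = patches, bn = bn, mask = mask, amax = amax,
                  dmask = dmask, n = n))
}

# Backward through pool/relu/bn to the convolution pre-activation,
# returned as an (n*P) x OC matrix.
conv_delta <- function(layer, params, ctx, e_out) {
  n <- ctx$n
  ix <- layer$idx
  d <- e_out
  if (!is.null(ctx$dmask)) d <- d * ctx$dmask
  if (layer$pool > 1) {
    dy <- matrix(0, n, ix$P * layer$out_channels)
    for (j in seq_len(nrow(ix$poolidx))) {
      cols <- ix$poolidx[j, ]
      dy[, cols] <- dy[, cols] + d * (ctx$amax == j)
    }
    d <- dy
  }
  dz <- matrix(as.vector(d), n * ix$P, layer$out_channels)
  if (!is.null(ctx$mask)) dz <- dz * ctx$mask
  dz
}

# Full batch-norm backward (through the batch statistics): for upstream grad u
# at the BN output, dL/dx = (gamma/sd) * (u - mean(u) - xhat * mean(u * xhat)),
# means taken over the batch-and-position dimension per channel.
bn_backward <- function(u, bn, gamma) {
  t1 <- sweep(u, 2L, colMeans(u))
  t2 <- bn$xhat * rep(colMeans(u * bn$xhat), each = nrow(u))
  sweep(t1 - t2, 2L, gamma * bn$scale, `*`)
}

conv_jtv <- function(layer, params, ctx, e_out) {
  n <- ctx$n
  ix <- layer$idx
  dz <- conv_delta(layer, params, ctx, e_out)
  if (layer$has_batchnorm)
    dz <- bn_backward(dz, ctx$bn, params$gamma)
  dpatch <- dz %*% t(params$W)  # (n*P) x kkC
  dxpad <- matrix(0, n, ix$Hp * ix$Wp * layer$in_shape[3])
  for (j in seq_len(ix$kkC)) {
    cols <- ix$colidx[j, ]
    dxpad[, cols] <- dxpad[, cols] + matrix(dpatch[, j], n, ix$P)
  }
  dxpad[, ix$interior, drop = FALSE]
}

conv_pgrad <- function(layer, params, ctx, e_out) {
  n <- ctx$n
  dz <- conv_delta(layer, params, ctx, e_out)
  g <- list()
  if (layer$has_batchnorm) {
    g$gamma <- colSums(dz * ctx$bn$xhat) / n
    g$beta <- colSums(dz) / n
    dz <- bn_backward(dz, ctx$bn, params$gamma)
  }
  g$W <- crossprod(ctx$patches, dz) / n
  g$b <- colSums(dz) / n
  g
}

# ---- dispatch --------------------------------------------------------------

layer_forward <- function(layer, params, x, training = FALSE, frozen = NULL) {
  if (ncol(x) != layer$d_in)
    stop("input width ", ncol(x), " does not match layer d_in ", layer$d_in)
  switch(layer$kind,
         affine = affine_forward(layer, params, x, training, frozen),
         conv_block = conv_forward(layer, params, x, training, frozen),
         stop("unknown layer kind: ", layer$kind))
}

layer_jtv <- function(layer, params, ctx, e_out) {
  switch(layer$kind,
         affine = affine_jtv(layer, params, ctx, e_out),
         conv_block = conv_jtv(layer, params, ctx, e_out))
}

layer_pgrad <- function(layer, params, ctx, e_out) {
  switch(layer$kind,
         affine = affine_pgrad(layer, params, ctx, e_out),
         conv_block = conv_pgrad(layer, params, ctx, e_out))
}

# Scaled uniform fan-in initialization for one layer.
layer_init <- function(layer) {
  if (layer$kind == "affine") {
    a <- 1 / sqrt(layer$d_in)
    list(W = matrix(stats::runif(layer$d_in * layer$d_out, -a, a), layer$d_in, layer$d_out),
         b = stats::runif(layer$d_out, -a, a))
  } else {
    kkC <- layer$idx$kkC
    a <- 1 / sqrt(kkC)
    p <- list(W = matrix(stats::runif(kkC * layer$out_channels, -a, a), kkC, layer$out_channels),
              b = stats::runif(layer$out_channels, -a, a))
    if (layer$has_batchnorm) {
      p$gamma <- rep(1, layer$out_channels)
      p$beta <- rep(0, layer$out_channels)
    }
    p
  }
}
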