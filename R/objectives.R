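# Classification objectives and their gradients with respect to the network
# output (logits). The gradient is what couples an objective into the
# predictive coding output node: e_L := d(loss)/d(vhat_L), sign-aligned with
# the e = prediction - target convention, so the squared-error objective
# reproduces the clamping behaviour exactly.

#' Output error node from an objective
#'
#' Returns the per-sample gradient of the objective with respect to the output
#' prediction. Supported objectives: `squared_error`, `cross_entropy`, `focal`,
#' `cb_focal`, `ldam`, `balanced_softmax`. Count-aware objectives require
#' `counts`, the per-class training sample counts.
#'
#' @param vhat_L Output predictions / logits (n x C).
#' @param y Target matrix (one-hot or soft, n x C).
#' @param objective Objective name.
#' @param gamma_f Focal focusing exponent (>= 0).
#' @param beta Class-balanced coefficient in `[0, 1)`.
#' @param C_margin LDAM margin scale (>= 0); margin for class j is
#'   `C_margin / counts_j^{1/4}`.
#' @param counts Per-class sample counts (length C).
#' @return An n x C error matrix.
#' @export
output_error_from_objective <- function(vhat_L, y, objective = "squared_error",
                                        gamma_f = 0, beta = 0, C_margin = 0,
                                        counts = NULL) {
  objective_eval(vhat_L, y, objective, gamma_f = gamma_f, beta = beta,
                 C_margin = C_margin, counts = counts)$grad
}

#' Objective loss value and gradient
#'
#' @inheritParams output_error_from_objective
#' @return `list(loss, grad)`: `loss` is the mean per-sample loss, `grad` the
#'   per-sample gradient with respect to the logits (n x C).
#' @export
objective_eval <- function(vhat_L, y, objective = "squared_error",
                           gamma_f = 0, beta = 0, C_margin = 0, counts = NULL) {
  if (is.null(dim(y))) y <- matrix(y, nrow = nrow(vhat_L))
  switch(objective,
    squared_error = {
      e <- vhat_L - y
      list(loss = sum(e^2) / (2 * nrow(e)), grad = e)
    },
    cross_entropy = ce_like(vhat_L, y),
    focal = focal_eval(vhat_L, y, gamma_f, weights = NULL),
    cb_focal = {
      if (is.null(counts)) stop("objective 'cb_focal' requires per-class counts")
      stopifnot(beta >= 0, beta < 1)
      ny <- as.vector(y %*% counts)  # count of each sample's true class
      w <- if (beta == 0) rep(1, length(ny)) else (1 - beta) / (1 - beta^ny)
      focal_eval(vhat_L, y, gamma_f, weights = w)
    },
    ldam = {
      if (is.null(counts)) stop("objective 'ldam' requires per-class counts")
      stopifnot(C_margin >= 0)
      margins <- C_margin / counts^(1 / 4)
      ce_like(vhat_L - y %*% diag(margins, length(margins)), y)
    },
    balanced_softmax = {
      if (is.null(counts)) stop("objective 'balanced_softmax' requires per-class counts")
      ce_like(sweep(vhat_L, 2L, log(counts), `+`), y)
    },
    stop("unknown objective: ", objective)
  )
}

# Softmax cross-entropy with (possibly soft) targets on shifted logits.
ce_like <- function(z, y) {
  p <- softmax_rows(z)
  list(loss = -mean(rowSums(y * log(pmax(p, 1e-300)))), grad = p - y)
}

# Focal loss -w (1-p_t)^gamma log p_t for one-hot targets; gamma_f = 0 reduces
# to cross-entropy (per-sample weights w for the class-balanced variant).
focal_eval <- function(z, y, gamma_f, weights = NULL) {
  stopifnot(gamma_f >= 0)
  if (gamma_f == 0) {
    r <- ce_like(z, y)
    if (!is.null(weights)) { r$loss <- mean(weights * ce_rows(z, y)); r$grad <- r$grad * weights }
    return(r)
  }
  p <- softmax_rows(z)
  pt <- pmin(pmax(rowSums(p * y), 1e-12), 1 - 1e-12)
  om <- 1 - pt
  loss_i <- -(om^gamma_f) * log(pt)
  # dL/dpt, then chain through dpt/dz_j = pt (y_j - p_j)
  dldpt <- gamma_f * om^(gamma_f - 1) * log(pt) - om^gamma_f / pt
  grad <- (dldpt * pt) * (y - p)
  if (!is.null(weights)) { loss_i <- weights * loss_i; grad <- grad * weights }
  list(loss = mean(loss_i), grad = grad)
}

ce_rows <- function(z, y) {
  p <- softmax_rows(z)
  -rowSums(y * log(pmax(p, 1e-300)))
}

#' Focal loss
#'
#' `-(1 - p_t)^{gamma_f} log p_t` with `p_t` the softmax probability of the
#' true class; `gamma_f = 0` reduces exactly to cross-entropy.
#'
#' @param logits n x C logit matrix.
#' @param target Integer labels (1..C) or one-hot matrix.
#' @param gamma_f Focusing exponent.
#' @return Mean loss (scalar).
#' @export
focal_loss <- function(logits, target, gamma_f) {
  y <- as_one_hot(target, ncol(logits))
  focal_eval(logits, y, gamma_f)$loss
}

#' Class-balanced focal loss
#'
#' Focal loss weighted per sample by the effective-number weight
#' `(1 - beta) / (1 - beta^{n_y})` of the sample's true class; `beta = 0`
#' reduces to the plain focal loss.
#'
#' @inheritParams focal_loss
#' @param beta Class-balanced coefficient in `[0, 1)`.
#' @param counts Per-class training counts.
#' @export
cb_focal_loss <- function(logits, target, beta, gamma_f, counts) {
  y <- as_one_hot(target, ncol(logits))
  objective_eval(logits, y, "cb_focal", gamma_f = gamma_f, beta = beta,
                 counts = counts)$loss
}

#' Label-distribution-aware margin (LDAM) loss
#'
#' Cross-entropy with a per-class margin `C_margin / n_j^{1/4}` subtracted from
#' the true-class logit, so rarer classes receive strictly larger margins;
#' `C_margin = 0` reduces to cross-entropy.
#'
#' @inheritParams cb_focal_loss
#' @param C_margin Margin scale.
#' @export
ldam_loss <- function(logits, target, C_margin, counts) {
  y <- as_one_hot(target, ncol(logits))
  objective_eval(logits, y, "ldam", C_margin = C_margin, counts = counts)$loss
}

#' Balanced-softmax loss
#'
#' `-log( n_y e^{z_y} / sum_j n_j e^{z_j} )`: softmax cross-entropy on logits
#' shifted by `log n_j`. With uniform counts it equals ordinary softmax
#' cross-entropy exactly (the common factor cancels). This is the
#' balanced-softmax term only; no meta-sampler is involved.
#'
#' @inheritParams cb_focal_loss
#' @export
balanced_softmax_loss <- function(logits, target, counts) {
  y <- as_one_hot(target, ncol(logits))
  objective_eval(logits, y, "balanced_softmax", counts = counts)$loss
}

as_one_hot <- function(target, C) {
  if (is.matrix(target)) target else one_hot(as.integer(target), C)
}

#' Mixup a pair of batches
#'
#' Convex combination `x = lam x1 + (1-lam) x2`, `y = lam y1 + (1-lam) y2`
#' with `lam ~ Beta(alpha, alpha)` drawn once per batch.
#'
#' @param x1,x2 Input matrices of identical shape.
#' @param y1,y2 One-hot / soft label matrices of identical shape.
#' @param alpha Beta concentration (> 0).
#' @param seed Optional integer seed; `lam` may also be supplied directly.
#' @param lam Optional fixed mixing coefficient in `[0, 1]`.
#' @return `list(x, y, lam)`; mixed labels stay row-stochastic.
#' @export
mixup_batch <- function(x1, y1, x2, y2, alpha = 1, seed = NULL, lam = NULL) {
  stopifnot(alpha > 0, all(dim(x1) == dim(x2)), all(dim(y1) == dim(y2)))
  if (is.null(lam)) {
    if (!is.null(seed)) set.seed(seed)
    lam <- stats::rbeta(1, alpha, alpha)
  }
  list(x = lam * x1 + (1 - lam) * x2, y = lam * y1 + (1 - lam) * y2, lam = lam)
}
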