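# The predictive coding engine: forward prediction, error nodes, variational
# free energy, iterative inference on activation nodes, and local weight
# updates, plus an exact chain-rule backpropagation oracle.
#
# Conventions (documented in the methods vignette):
#   * error sign: e_i = prediction - activation (e_i = vhat_i - v_i);
#   * free energy F = 1/2 * sum_i ||e_i||^2, averaged over the minibatch, so
#     that equilibrium weight updates match gradients of the standard
#     1/2-squared-error loss without a factor-of-two mismatch;
#   * inference update dv_i = e_i - J_{i+1}^T e_{i+1} (= -dF/dv_i);
#   * gradient sets hold *descent* increments: theta <- theta + eta * dtheta.

#' Forward phase: compute predictions layer by layer
#'
#' Runs the feedforward sweep `vhat_i = f_i(vhat_{i-1}; theta_i)`, initializes
#' every activation node at its prediction (`v_i := vhat_i`), and zeroes all
#' error nodes, so the returned state has free energy 0 until a target is
#' clamped. In training mode dropout masks (and batch-norm statistics) are
#' drawn once and frozen in the state for the whole minibatch.
#'
#' @param spec A `pcnet_spec`.
#' @param params Matching `pcnet_params`.
#' @param x Input matrix (n x input_dim); a vector is treated as one row.
#' @param training Draw dropout masks / use batch statistics for this batch.
#' @return A `pcnet_state` with activations `v` (layers 0..L), predictions
#'   `vhat` and errors `e` (layers 1..L), and per-layer frozen context.
#' @export
forward_pass <- function(spec, params, x, training = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != spec$input_dim)
    stop("input width ", ncol(x), " does not match spec input_dim ", spec$input_dim)
  L <- spec$n_layers
  v <- vector("list", L + 1L)
  vhat <- vector("list", L)
  e <- vector("list", L)
  ctx <- vector("list", L)
  v[[1L]] <- x
  cur <- x
  for (i in seq_len(L)) {
    fw <- layer_forward(spec$layers[[i]], params[[i]], cur, training = training)
    vhat[[i]] <- fw$out
    ctx[[i]] <- fw$ctx
    v[[i + 1L]] <- fw$out
    e[[i]] <- matrix(0, nrow(fw$out), ncol(fw$out))
    cur <- fw$out
  }
  structure(list(v = v, vhat = vhat, e = e, ctx = ctx, n = nrow(x),
                 target = NULL, coupling = NULL, clamped = FALSE),
            class = "pcnet_state")
}

#' @export
print.pcnet_state <- function(x, ...) {
  L <- length(x$vhat)
  cat("pcnet state: ", L, " layers, batch ", x$n,
      ", F = ", format(free_energy(x)), "\n", sep = "")
  invisible(x)
}

#' Clamp the output node to a target / couple an objective
#'
#' For the squared-error objective the output activation is clamped to the
#' target (`v_L := y`, error `e_L = vhat_L - y`), exactly the output-error step
#' of the incremental-learning algorithm. For any other objective the output
#' error node is set directly to the objective's gradient with respect to the
#' prediction (sign-aligned with `e = prediction - target`), and `v_L` stays
#' unclamped.
#'
#' @param state A `pcnet_state` from [forward_pass()].
#' @param y Target matrix (one-hot or soft labels, n x output_dim) or an
#'   integer label vector (converted to one-hot).
#' @param objective Objective name (see [output_error_from_objective()]).
#' @param ... Objective parameters (e.g. `gamma_f`, `beta`, `C`, `counts`).
#' @return The updated state.
#' @export
clamp_target <- function(state, y, objective = "squared_error", ...) {
  L <- length(state$vhat)
  C <- ncol(state$vhat[[L]])
  if (is.null(dim(y)) && !is.matrix(y)) {
    if (length(y) == state$n && C > 1 && all(y == round(y)))
      y <- one_hot(as.integer(y), C)
    else y <- matrix(y, nrow = state$n)
  }
  if (!all(dim(y) == dim(state$vhat[[L]])))
    stop("target shape (", paste(dim(y), collapse = "x"),
         ") does not match output layer (", paste(dim(state$vhat[[L]]), collapse = "x"), ")")
  state$target <- y
  if (identical(objective, "squared_error")) {
    state$clamped <- TRUE
    state$coupling <- NULL
    state$v[[L + 1L]] <- y
    state$e[[L]] <- state$vhat[[L]] - y
  } else {
    state$clamped <- FALSE
    state$coupling <- list(objective = objective, args = list(...))
    state$e[[L]] <- output_error_from_objective(state$vhat[[L]], y, objective, ...)
  }
  state
}

#' Variational free energy of a state
#'
#' `F = 1/2 * sum_{i=1..L} ||e_i||^2`, averaged over the minibatch dimension.
#' Nonnegative and additive over layers by construction.
#'
#' @param state A `pcnet_state`.
#' @return Scalar free energy.
#' @export
free_energy <- function(state) {
  sum(vapply(state$e, function(ei) sum(ei^2), numeric(1))) / (2 * state$n)
}

#' One iteration of inference on the activation nodes
#'
#' Updates every unclamped hidden activation by gradient descent on the free
#' energy: `v_i <- v_i + eta_v * (e_i - J_{i+1}^T e_{i+1})`. Under the fixed
#' prediction assumption (the default) predictions and Jacobians stay frozen at
#' their feedforward values and only the error identity `e_i = vhat_i - v_i` is
#' refreshed; otherwise predictions, Jacobians, and the output coupling are
#' re-evaluated at the current activations (dropout masks and batch statistics
#' stay frozen per minibatch, so the loop is deterministic).
#'
#' @param state A clamped/coupled `pcnet_state`.
#' @param spec,params Network description and parameters.
#' @param eta_v Positive inference learning rate.
#' @param fixed_predictions Freeze predictions and Jacobians at feedforward values.
#' @return The updated state, with attribute `"dv_max"` holding the max-norm of
#'   the activation increments (the convergence statistic).
#' @export
inference_step <- function(state, spec, params, eta_v = 0.1, fixed_predictions = TRUE) {
  stopifnot(eta_v > 0)
  L <- spec$n_layers
  dv_max <- 0
  if (L >= 2) {
    for (i in seq_len(L - 1L)) {
      jt <- layer_jtv(spec$layers[[i + 1L]], params[[i + 1L]], state$ctx[[i + 1L]],
                      state$e[[i + 1L]])
      dv <- state$e[[i]] - jt
      state$v[[i + 1L]] <- state$v[[i + 1L]] + eta_v * dv
      dv_max <- max(dv_max, max(abs(dv)))
    }
  }
  if (!fixed_predictions) {
    # re-evaluate predictions and Jacobians at the current activations
    for (i in seq_len(L)) {
      fw <- layer_forward(spec$layers[[i]], params[[i]], state$v[[i]],
                          frozen = state$ctx[[i]])
      state$vhat[[i]] <- fw$out
      state$ctx[[i]] <- fw$ctx
    }
    if (state$clamped) state$v[[L + 1L]] <- state$target
    if (!is.null(state$coupling))
      state$e[[L]] <- do.call(output_error_from_objective,
                              c(list(state$vhat[[L]], state$target,
                                     state$coupling$objective), state$coupling$args))
  }
  # refresh hidden errors against (possibly frozen) predictions
  upto <- if (state$clamped && is.null(state$coupling)) L else L - 1L
  for (i in seq_len(max(upto, 0L)))
    state$e[[i]] <- state$vhat[[i]] - state$v[[i + 1L]]
  if (fixed_predictions && state$clamped)
    state$e[[L]] <- state$vhat[[L]] - state$target
  for (i in seq_len(L)) {
    if (anyNA(state$e[[i]]) || any(!is.finite(state$e[[i]])))
      stop("non-finite values in error node of layer ", i, " during inference")
  }
  attr(state, "dv_max") <- dv_max
  state
}

#' Run the backward (inference) phase
#'
#' Repeats [inference_step()] until `max_iters` is reached or the max-norm of
#' all activation increments drops below `tol`, recording the free energy after
#' every iteration. The default is a fixed budget of 20 iterations, the
#' convention used throughout the experiments; `tol > 0` enables early stop.
#'
#' @inheritParams inference_step
#' @param max_iters Maximum number of iterations (default 20).
#' @param tol Nonnegative early-stop threshold on the activation increments.
#' @param explosion Diagnostic threshold: if F exceeds `explosion * (F0 + 1)`
#'   the run aborts with an error reporting `eta_v` and the iteration.
#' @return `list(state, trace, iterations, converged)` where `trace` is the
#'   per-iteration free-energy sequence (an energy trace).
#' @export
run_inference <- function(state, spec, params, eta_v = 0.1, max_iters = 20L,
                          tol = 0, fixed_predictions = TRUE, explosion = 1e6) {
  stopifnot(max_iters >= 1, tol >= 0)
  f0 <- free_energy(state)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iters) {
    it <- it + 1L
    state <- inference_step(state, spec, params, eta_v, fixed_predictions)
    f <- free_energy(state)
    trace <- c(trace, f)
    if (!is.finite(f) || f > explosion * (f0 + 1))
      stop("free energy diverged (F = ", format(f), ") at iteration ", it,
           " with eta_v = ", eta_v)
    if (attr(state, "dv_max") < tol) { converged <- TRUE; break }
  }
  list(state = state, trace = trace, iterations = it, converged = converged)
}

#' Local weight gradients at (approximate) equilibrium
#'
#' The local learning rule: for each layer,
#' `dtheta_i = -e_i * d f_i(v_{i-1}; theta_i) / d theta_i`, a function only of
#' the layer's own error node and its frozen input context — no quantity from
#' any non-adjacent layer is read. Returned increments are descent directions
#' (apply with [apply_update()]), averaged over the minibatch.
#'
#' @param state A `pcnet_state` after inference.
#' @param spec,params Network description and parameters.
#' @param use_relaxed Evaluate the presynaptic factor at the relaxed
#'   activations `v_{i-1}` (the Hebbian reading of the local rule) instead of
#'   the frozen feedforward values. The frozen form (default) is the one under
#'   which fixed-prediction equilibrium updates equal backpropagation exactly;
#'   the relaxed form matches the update rule as the learning algorithm states
#'   it and differs from backpropagation by an error-correlation term.
#' @return A `pcnet_grads` list with the same shapes as `params`.
#' @export
weight_gradient <- function(state, spec, params, use_relaxed = FALSE) {
  g <- vector("list", spec$n_layers)
  for (i in seq_len(spec$n_layers)) {
    ctx <- state$ctx[[i]]
    if (use_relaxed && i > 1) {
      fw <- layer_forward(spec$layers[[i]], params[[i]], state$v[[i]],
                          frozen = state$ctx[[i]])
      ctx <- fw$ctx
      ctx$mask <- state$ctx[[i]]$mask
      ctx$amax <- state$ctx[[i]]$amax
    }
    gi <- layer_pgrad(spec$layers[[i]], params[[i]], ctx, state$e[[i]])
    g[[i]] <- lapply(gi, function(x) -x)
  }
  structure(g, class = "pcnet_grads")
}

#' Apply a gradient-set update to the parameters
#'
#' `theta <- theta + eta_theta * dtheta - eta_theta * weight_decay * theta`
#' (decay applied to weight matrices only, not biases or batch-norm shifts).
#'
#' @param params A `pcnet_params` list.
#' @param grads A matching `pcnet_grads` list of descent increments.
#' @param eta_theta Positive weight learning rate.
#' @param weight_decay Nonnegative decoupled weight-decay coefficient.
#' @return Updated parameters.
#' @export
apply_update <- function(params, grads, eta_theta, weight_decay = 0) {
  stopifnot(length(params) == length(grads))
  for (i in seq_along(params)) {
    for (nm in names(grads[[i]])) {
      if (!all(dim(params[[i]][[nm]]) == dim(grads[[i]][[nm]])) &&
          length(params[[i]][[nm]]) != length(grads[[i]][[nm]]))
        stop("gradient shape mismatch in layer ", i, " parameter ", nm)
      params[[i]][[nm]] <- params[[i]][[nm]] + eta_theta * grads[[i]][[nm]]
      if (weight_decay > 0 && nm == "W")
        params[[i]][[nm]] <- params[[i]][[nm]] - eta_theta * weight_decay * params[[i]][[nm]]
    }
  }
  params
}

#' Exact chain-rule gradients (backpropagation oracle)
#'
#' Computes the output error from the objective, then propagates deltas in
#' reverse layer order. Serves both as the baseline training algorithm and as
#' the oracle in fixed-prediction equivalence tests. Returned increments are
#' descent directions, batch-averaged, identical in convention to
#' [weight_gradient()].
#'
#' @inheritParams forward_pass
#' @param y Target (one-hot / soft matrix or integer labels).
#' @param objective Objective name.
#' @param state Optional precomputed `pcnet_state` (to share dropout masks and
#'   batch statistics with a PC step on the same minibatch).
#' @param ... Objective parameters.
#' @return A `pcnet_grads` list.
#' @export
bp_gradient <- function(spec, params, x, y, objective = "squared_error",
                        state = NULL, training = FALSE, ...) {
  if (is.null(state)) state <- forward_pass(spec, params, x, training = training)
  L <- spec$n_layers
  C <- ncol(state$vhat[[L]])
  if (is.null(dim(y)) && length(y) == state$n && C > 1 && all(y == round(y)))
    y <- one_hot(as.integer(y), C)
  if (is.null(dim(y))) y <- matrix(y, nrow = state$n)
  delta <- output_error_from_objective(state$vhat[[L]], y, objective, ...)
  g <- vector("list", L)
  for (i in rev(seq_len(L))) {
    gi <- layer_pgrad(spec$layers[[i]], params[[i]], state$ctx[[i]], delta)
    g[[i]] <- lapply(gi, function(v) -v)
    if (i > 1)
      delta <- layer_jtv(spec$layers[[i]], params[[i]], state$ctx[[i]], delta)
  }
  structure(g, class = "pcnet_grads")
}

#' One-call predictive coding gradient
#'
#' Convenience wrapper: forward phase, output clamp/coupling, inference run,
#' local weight gradients.
#'
#' @inheritParams bp_gradient
#' @inheritParams run_inference
#' @return `list(grads, state, trace, iterations, converged)`.
#' @export
pc_gradient <- function(spec, params, x, y, objective = "squared_error",
                        eta_v = 0.1, max_iters = 20L, tol = 0,
                        fixed_predictions = TRUE, use_relaxed = FALSE,
                        state = NULL, training = FALSE, ...) {
  if (is.null(state)) state <- forward_pass(spec, params, x, training = training)
  state <- clamp_target(state, y, objective, ...)
  inf <- run_inference(state, spec, params, eta_v = eta_v, max_iters = max_iters,
                       tol = tol, fixed_predictions = fixed_predictions)
  list(grads = weight_gradient(inf$state, spec, params, use_relaxed = use_relaxed),
       state = inf$state,
       trace = inf$trace, iterations = inf$iterations, converged = inf$converged)
}

#' Predict class labels / network outputs
#'
#' Deterministic evaluation-mode forward pass, chunked at a fixed batch size so
#' batch-norm statistics (computed per chunk) are reproducible.
#'
#' @inheritParams forward_pass
#' @param chunk Evaluation chunk size.
#' @return Matrix of network outputs (n x output_dim).
#' @export
predict_outputs <- function(spec, params, x, chunk = 256L) {
  n <- nrow(x)
  out <- matrix(0, n, spec$output_dim)
  start <- 1L
  while (start <= n) {
    end <- min(start + chunk - 1L, n)
    st <- forward_pass(spec, params, x[start:end, , drop = FALSE], training = FALSE)
    out[start:end, ] <- st$vhat[[spec$n_layers]]
    start <- end + 1L
  }
  out
}

#' @rdname predict_outputs
#' @return `predict_classes` returns integer labels in 1..output_dim.
#' @export
predict_classes <- function(spec, params, x, chunk = 256L) {
  max.col(predict_outputs(spec, params, x, chunk), ties.method = "first")
}
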