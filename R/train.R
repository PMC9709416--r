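# Shared minibatch training engine for both learning algorithms. The two
# algorithms differ only in how the per-batch weight increment is produced:
# "bp" uses exact chain-rule gradients; "pc" runs the inference loop (default
# 20 iterations, fixed prediction assumption) and applies the local rule.

#' Reduce-on-plateau learning-rate schedule step
#'
#' After five consecutive epochs without improvement in the validation loss
#' the learning rate is multiplied by 1/3, clipped below at the floor
#' (default 1e-4); the counter resets on improvement and on decay.
#'
#' @param state A schedule state from [plateau_state()].
#' @param val_loss Finite validation loss for the epoch.
#' @return The updated schedule state.
#' @export
plateau_schedule <- function(state, val_loss) {
  stopifnot(is.finite(val_loss))
  if (val_loss < state$best_loss - state$min_delta) {
    state$best_loss <- val_loss
    state$counter <- 0L
  } else {
    state$counter <- state$counter + 1L
    if (state$counter >= state$patience) {
      state$lr <- max(state$lr / 3, state$floor)
      state$counter <- 0L
    }
  }
  state
}

#' @rdname plateau_schedule
#' @param lr Initial learning rate.
#' @param floor Minimum learning rate (default 1e-4).
#' @param patience Non-improving epochs before decay (default 5).
#' @param min_delta Minimum improvement to reset the counter.
#' @export
plateau_state <- function(lr, floor = 1e-4, patience = 5L, min_delta = 0) {
  list(lr = lr, floor = floor, patience = as.integer(patience),
       best_loss = Inf, counter = 0L, min_delta = min_delta)
}

#' Train a classifier by minibatch gradient descent
#'
#' @param spec,params Network description and initial parameters.
#' @param x,y Training inputs (n x d) and integer labels (1..n_classes).
#' @param n_classes Size of the (shared) classifier head.
#' @param algorithm `"bp"` (chain rule) or `"pc"` (inference + local rule).
#' @param objective Objective coupled at the output; defaults to the
#'   squared-error clamp for PC and softmax cross-entropy for BP.
#' @param epochs,batch_size Training length and minibatch size.
#' @param lr Weight learning rate (eta_theta for PC).
#' @param eta_v,pc_iters,fixed_predictions Inference-loop settings for PC.
#' @param weight_decay Decoupled weight decay on weight matrices.
#' @param schedule `"plateau"` (divide by 3 after 5 flat epochs, floor 1e-4),
#'   `"step"` (multiply by `step_factor` every `step_every` epochs), or
#'   `"none"`.
#' @param step_every,step_factor,lr_floor Schedule parameters.
#' @param seed Integer seed controlling shuffling and dropout.
#' @param x_val,y_val Optional validation split (drives the plateau schedule
#'   and best-model tracking; training loss is used if absent).
#' @param mixup_alpha If non-NULL, apply mixup within each minibatch with this
#'   Beta concentration (objective evaluated on soft targets).
#' @param grad_hook Optional `function(grads, params)` applied to each batch's
#'   gradient set (e.g. a consolidation penalty).
#' @param epoch_hook Optional `function(params, epoch)` called after each epoch.
#' @param objective_args Extra objective parameters (counts, gamma_f, ...).
#' @return `list(params, best_params, best_val_acc, history)`; `history` is a
#'   data frame with per-epoch lr, losses and validation accuracy.
#' @export
sgd_train <- function(spec, params, x, y, n_classes,
                      algorithm = c("bp", "pc"),
                      objective = NULL,
                      epochs = 20L, batch_size = 64L, lr = 0.05,
                      eta_v = 0.1, pc_iters = 20L, fixed_predictions = TRUE,
                      pc_use_relaxed = FALSE, weight_decay = 0,
                      schedule = c("plateau", "step", "none"),
                      step_every = 20L, step_factor = 0.1, lr_floor = 1e-4,
                      seed = 1L, x_val = NULL, y_val = NULL,
                      mixup_alpha = NULL, grad_hook = NULL, epoch_hook = NULL,
                      objective_args = list()) {
  algorithm <- match.arg(algorithm)
  schedule <- match.arg(schedule)
  if (is.null(objective))
    objective <- if (algorithm == "pc") "squared_error" else "cross_entropy"
  if (nrow(x) == 0) stop("sgd_train: empty training set")
  sched <- plateau_state(lr, floor = lr_floor)
  best_params <- params
  best_val_acc <- -Inf
  hist <- vector("list", epochs)
  yh <- one_hot(y, n_classes)
  for (ep in seq_len(epochs)) {
    set.seed(derive_seed(seed, ep))
    batches <- minibatch_indices(nrow(x), batch_size)
    tr_loss <- 0
    for (b in batches) {
      xb <- x[b, , drop = FALSE]
      yb <- yh[b, , drop = FALSE]
      if (!is.null(mixup_alpha)) {
        perm <- sample(length(b))
        mx <- mixup_batch(xb, yb, xb[perm, , drop = FALSE], yb[perm, , drop = FALSE],
                          alpha = mixup_alpha)
        xb <- mx$x; yb <- mx$y
      }
      state <- forward_pass(spec, params, xb, training = TRUE)
      L <- spec$n_layers
      ev <- do.call(objective_eval,
                    c(list(state$vhat[[L]], yb, objective), objective_args))
      tr_loss <- tr_loss + ev$loss * length(b)
      grads <- if (algorithm == "bp") {
        do.call(bp_gradient, c(list(spec, params, xb, yb, objective, state = state),
                               objective_args))
      } else {
        do.call(pc_gradient, c(list(spec, params, xb, yb, objective,
                                    eta_v = eta_v, max_iters = pc_iters,
                                    fixed_predictions = fixed_predictions,
                                    use_relaxed = pc_use_relaxed,
                                    state = state), objective_args))$grads
      }
      if (!is.null(grad_hook)) grads <- grad_hook(grads, params)
      params <- apply_update(params, grads, sched$lr, weight_decay)
    }
    tr_loss <- tr_loss / nrow(x)
    if (!is.null(x_val)) {
      vout <- predict_outputs(spec, params, x_val)
      vloss <- do.call(objective_eval,
                       c(list(vout, one_hot(y_val, n_classes), objective),
                         objective_args))$loss
      vacc <- accuracy_pct(max.col(vout, ties.method = "first"), y_val)
    } else {
      vloss <- tr_loss
      vacc <- NA_real_
    }
    if (is.na(vacc) || vacc >= best_val_acc) {
      best_val_acc <- if (is.na(vacc)) -Inf else vacc
      best_params <- params
    }
    lr_used <- sched$lr
    # a non-finite validation loss (diverged run) counts as a non-improving epoch
    if (schedule == "plateau")
      sched <- plateau_schedule(sched, if (is.finite(vloss)) vloss else sched$best_loss + 1)
    else if (schedule == "step" && ep %% step_every == 0)
      sched$lr <- max(sched$lr * step_factor, 0)
    hist[[ep]] <- data.frame(epoch = ep, lr = lr_used, train_loss = tr_loss,
                             val_loss = vloss, val_acc = vacc)
    if (!is.null(epoch_hook)) epoch_hook(params, ep)
  }
  list(params = params, best_params = best_params, best_val_acc = best_val_acc,
       history = do.call(rbind, hist))
}
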