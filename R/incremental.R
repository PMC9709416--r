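# Class-incremental learning: task-sequence construction, strictly sequential
# training with no access to earlier tasks' data, forgetting evaluation, and
# consolidation variants (elastic weight consolidation and incremental moment
# matching) usable under both learning algorithms.

#' Build a class-incremental task sequence
#'
#' `"disjoint"` splits the label set into 2 tasks of `C/2` classes in label
#' order; `"split"` into `C/2` tasks of 2 consecutive classes. Tasks carry
#' train/test index lists into the supplied label vectors; class sets are
#' pairwise disjoint and cover the label set.
#'
#' @param train_y,test_y Integer label vectors (1..C) for the train/test pools.
#' @param scheme `"disjoint"` or `"split"`.
#' @param seed Seed for the optional per-class subsampling.
#' @param per_class_quota Optional cap on training samples per class
#'   (seeded uniform subsample).
#' @return A `pcnet_tasks` list; each task has `classes`, `train_idx`,
#'   `test_idx`.
#' @export
build_task_sequence <- function(train_y, test_y, scheme = c("disjoint", "split"),
                                seed = 1L, per_class_quota = NULL) {
  scheme <- match.arg(scheme)
  labels <- sort(unique(c(train_y, test_y)))
  C <- length(labels)
  per_task <- if (scheme == "disjoint") C %/% 2L else 2L
  if (C %% per_task != 0)
    stop("label count ", C, " not divisible by per-task class count ", per_task)
  n_tasks <- C %/% per_task
  set.seed(seed)
  tasks <- vector("list", n_tasks)
  for (t in seq_len(n_tasks)) {
    cls <- labels[((t - 1L) * per_task + 1L):(t * per_task)]
    tr <- which(train_y %in% cls)
    if (!is.null(per_class_quota)) {
      keep <- unlist(lapply(cls, function(cl) {
        idx <- tr[train_y[tr] == cl]
        if (length(idx) > per_class_quota) sort(sample(idx, per_class_quota)) else idx
      }))
      tr <- sort(keep)
    }
    tasks[[t]] <- list(classes = cls, train_idx = tr,
                       test_idx = which(test_y %in% cls))
  }
  structure(tasks, class = "pcnet_tasks", scheme = scheme)
}

#' Evaluate accuracy on all seen tasks
#'
#' One row of the (task-trained x task-evaluated) accuracy matrix: held-out
#' accuracy in percent for every task up to `up_to_task`.
#'
#' @param spec,params Network and parameters.
#' @param tasks A `pcnet_tasks` sequence.
#' @param test_data Test dataset (`x`, `y`).
#' @param up_to_task Number of tasks seen so far.
#' @param restrict_to_task Score each task's samples by argmax over that
#'   task's own classes (default). The network always trains a single shared
#'   head over all classes; restricted scoring measures how well task
#'   knowledge (features and that task's head rows) survives later training,
#'   the protocol behind per-task accuracy tables. Set `FALSE` for the
#'   stricter all-class argmax.
#' @return Numeric vector of length `up_to_task` (accuracies in percent).
#' @export
evaluate_all_tasks <- function(spec, params, tasks, test_data, up_to_task,
                               restrict_to_task = TRUE) {
  vapply(seq_len(up_to_task), function(t) {
    idx <- tasks[[t]]$test_idx
    out <- predict_outputs(spec, params, test_data$x[idx, , drop = FALSE])
    pred <- if (restrict_to_task) {
      cls <- tasks[[t]]$classes
      cls[max.col(out[, cls, drop = FALSE], ties.method = "first")]
    } else max.col(out, ties.method = "first")
    accuracy_pct(pred, test_data$y[idx])
  }, numeric(1))
}

#' Average accuracy over a final evaluation row
#'
#' Unweighted arithmetic mean of the per-task accuracies (the "Average"
#' column); reporting rounds half up to 2 decimals via [round_half_up()].
#'
#' @param row Numeric vector of per-task accuracies.
#' @return Scalar mean accuracy (unrounded).
#' @export
average_accuracy <- function(row) {
  if (length(row) == 0) stop("average_accuracy: empty row")
  mean(row)
}

#' Task-1 forgetting of an evaluation matrix
#'
#' Drop of task-1 accuracy from its just-trained (diagonal) value to its value
#' after the final task.
#'
#' @param mat Evaluation matrix as a list of rows (row t has t entries).
#' @return Forgetting in percentage points.
#' @export
task1_forgetting <- function(mat) {
  mat[[1]][1] - mat[[length(mat)]][1]
}

# ---- consolidation ---------------------------------------------------------

#' Diagonal Fisher information estimate
#'
#' Per-parameter average of squared per-sample objective gradients, estimated
#' on (a subsample of) a task's training data.
#'
#' @param spec,params Network and parameters.
#' @param x,y Task data and integer labels.
#' @param n_classes Head size.
#' @param objective Objective whose gradients are squared.
#' @param n_samples Maximum number of samples used.
#' @param seed Subsampling seed.
#' @return A gradient-shaped list of nonnegative Fisher diagonals.
#' @export
fisher_diag <- function(spec, params, x, y, n_classes,
                        objective = "cross_entropy", n_samples = 200L, seed = 1L) {
  set.seed(seed)
  idx <- if (nrow(x) > n_samples) sample(nrow(x), n_samples) else seq_len(nrow(x))
  acc <- NULL
  for (i in idx) {
    g <- bp_gradient(spec, params, x[i, , drop = FALSE],
                     one_hot(y[i], n_classes), objective)
    g2 <- lapply(g, function(l) lapply(l, function(v) v^2))
    acc <- if (is.null(acc)) g2 else
      mapply(function(a, b) mapply(`+`, a, b, SIMPLIFY = FALSE), acc, g2,
             SIMPLIFY = FALSE)
  }
  lapply(acc, function(l) lapply(l, function(v) v / length(idx)))
}

#' Elastic weight consolidation penalty
#'
#' Builds the quadratic-anchor penalty `lambda/2 * sum_k F_k (theta - theta*_k)^2`
#' after a task, and the gradient hook that adds its descent direction to each
#' layer's local increment (applies identically under both algorithms).
#'
#' @param anchors List of `list(params, fisher)` snapshots, one per past task.
#' @param lambda Penalty strength (>= 0).
#' @return `function(grads, params)` adding the penalty gradient.
#' @export
ewc_hook <- function(anchors, lambda) {
  if (lambda < 0) stop("ewc_hook: lambda must be nonnegative")
  function(grads, params) {
    if (lambda == 0 || length(anchors) == 0) return(grads)
    for (a in anchors) {
      for (i in seq_along(grads)) {
        for (nm in names(grads[[i]])) {
          grads[[i]][[nm]] <- grads[[i]][[nm]] -
            lambda * a$fisher[[i]][[nm]] * (params[[i]][[nm]] - a$params[[i]][[nm]])
        }
      }
    }
    grads
  }
}

#' Incremental moment matching merge
#'
#' `mode = "mean"`: unweighted average of the per-task parameter snapshots.
#' `mode = "mode"`: Fisher-precision-weighted average
#' `theta = sum_k F_k theta_k / sum_k F_k` (with a small regularizer in the
#' denominator).
#'
#' @param snapshots List of `pcnet_params` of identical shapes.
#' @param mode `"mean"` or `"mode"`.
#' @param fishers List of Fisher diagonals (required for `"mode"`).
#' @param eps Denominator regularizer.
#' @return Merged `pcnet_params`.
#' @export
imm_merge <- function(snapshots, mode = c("mean", "mode"), fishers = NULL,
                      eps = 1e-8) {
  mode <- match.arg(mode)
  stopifnot(length(snapshots) >= 1)
  K <- length(snapshots)
  out <- snapshots[[1]]
  for (i in seq_along(out)) {
    for (nm in names(out[[i]])) {
      dims <- lapply(snapshots, function(s) length(s[[i]][[nm]]))
      if (length(unique(unlist(dims))) != 1)
        stop("imm_merge: shape mismatch in layer ", i, " parameter ", nm)
      if (mode == "mean") {
        acc <- 0
        for (k in seq_len(K)) acc <- acc + snapshots[[k]][[i]][[nm]]
        out[[i]][[nm]] <- acc / K
      } else {
        if (is.null(fishers)) stop("imm_merge: mode merge requires fishers")
        num <- 0; den <- 0
        for (k in seq_len(K)) {
          num <- num + fishers[[k]][[i]][[nm]] * snapshots[[k]][[i]][[nm]]
          den <- den + fishers[[k]][[i]][[nm]]
        }
        out[[i]][[nm]] <- num / (den + eps)
      }
    }
  }
  out
}

# ---- sequential training ---------------------------------------------------

#' Default incremental-learning configuration
#'
#' Weight learning rate 0.1 for PC and initial rate 0.05 for BP, batch size 64,
#' reduce-on-plateau schedule (divide by 3 after 5 flat validation epochs,
#' floor 1e-4), 20 inference iterations under the fixed prediction assumption.
#'
#' @param algorithm `"bp"` or `"pc"`.
#' @param ... Overrides.
#' @return A configuration list.
#' @export
incremental_config <- function(algorithm = "bp", ...) {
  cfg <- list(lr = if (algorithm == "pc") 0.1 else 0.05, batch_size = 64L,
              epochs_per_task = 20L, eta_v = 0.1, pc_iters = 20L,
              fixed_predictions = TRUE, pc_use_relaxed = FALSE, val_fraction = 0.1,
              objective = "cross_entropy",
              ewc_lambda = 100, fisher_samples = 200L, weight_decay = 0)
  utils::modifyList(cfg, list(...))
}

#' Sequential (class-incremental) training
#'
#' Trains the tasks strictly in order with no access to earlier tasks' data.
#' Within each task a seeded validation split drives the plateau schedule and
#' best-model selection; after each task, all seen tasks are evaluated with the
#' task's best-validation model (the table protocol), and per-epoch evaluations
#' of all seen tasks are recorded (the curve protocol). A single shared
#' classifier head over all classes is used throughout.
#'
#' @param spec Network specification.
#' @param tasks A `pcnet_tasks` sequence.
#' @param train_data,test_data Datasets (`x`, `y`, `n_classes`).
#' @param algorithm `"bp"` or `"pc"`.
#' @param method `"sgd"`, `"ewc"`, `"imm_mean"`, or `"imm_mode"`.
#' @param config From [incremental_config()].
#' @param seeds Integer vector of seeds (experiments default to 5).
#' @param track_curves Record per-epoch evaluations of all seen tasks.
#' @return A `pcnet_incremental` result: per-seed evaluation matrices, final
#'   rows, average accuracies, forgetting, and epoch histories.
#' @export
train_sequential <- function(spec, tasks, train_data, test_data,
                             algorithm = c("bp", "pc"),
                             method = c("sgd", "ewc", "imm_mean", "imm_mode"),
                             config = incremental_config(algorithm),
                             seeds = 1:5, track_curves = FALSE) {
  algorithm <- match.arg(algorithm)
  method <- match.arg(method)
  if (any(vapply(tasks, function(t) length(t$train_idx), integer(1)) == 0))
    stop("train_sequential: empty task")
  n_tasks <- length(tasks)
  per_seed <- vector("list", length(seeds))
  for (s in seq_along(seeds)) {
    seed <- seeds[s]
    params <- init_params(spec, seed)
    anchors <- list()
    snapshots <- list()
    fishers <- list()
    eval_matrix <- vector("list", n_tasks)
    curves <- list()
    histories <- list()
    for (t in seq_len(n_tasks)) {
      idx <- tasks[[t]]$train_idx
      set.seed(derive_seed(seed, 1000 + t))
      nval <- max(1L, floor(length(idx) * config$val_fraction))
      vidx <- sample(idx, nval)
      tidx <- setdiff(idx, vidx)
      hook <- if (method == "ewc") ewc_hook(anchors, config$ewc_lambda) else NULL
      curve_rows <- list()
      epoch_hook <- if (track_curves) function(p, ep) {
        curve_rows[[length(curve_rows) + 1L]] <<-
          data.frame(task = t, epoch = ep,
                     eval_task = seq_len(t),
                     accuracy = evaluate_all_tasks(spec, p, tasks, test_data, t))
      } else NULL
      fit <- sgd_train(spec, params,
                       train_data$x[tidx, , drop = FALSE], train_data$y[tidx],
                       n_classes = train_data$n_classes,
                       algorithm = algorithm, objective = config$objective,
                       epochs = config$epochs_per_task,
                       batch_size = config$batch_size, lr = config$lr,
                       eta_v = config$eta_v, pc_iters = config$pc_iters,
                       fixed_predictions = config$fixed_predictions,
                       pc_use_relaxed = config$pc_use_relaxed,
                       weight_decay = config$weight_decay,
                       schedule = "plateau", seed = derive_seed(seed, t),
                       x_val = train_data$x[vidx, , drop = FALSE],
                       y_val = train_data$y[vidx],
                       grad_hook = hook, epoch_hook = epoch_hook)
      params <- fit$params
      histories[[t]] <- transform(fit$history, task = t)
      if (track_curves) curves[[t]] <- do.call(rbind, curve_rows)
      eval_params <- fit$best_params
      if (method == "ewc") {
        anchors[[length(anchors) + 1L]] <- list(
          params = params,
          fisher = fisher_diag(spec, params,
                               train_data$x[idx, , drop = FALSE], train_data$y[idx],
                               train_data$n_classes, config$objective,
                               config$fisher_samples, seed = derive_seed(seed, 2000 + t)))
      }
      if (method %in% c("imm_mean", "imm_mode")) {
        snapshots[[t]] <- fit$best_params
        if (method == "imm_mode")
          fishers[[t]] <- fisher_diag(spec, fit$best_params,
                                      train_data$x[idx, , drop = FALSE],
                                      train_data$y[idx], train_data$n_classes,
                                      config$objective, config$fisher_samples,
                                      seed = derive_seed(seed, 3000 + t))
        eval_params <- if (t == 1) snapshots[[1]] else
          imm_merge(snapshots, if (method == "imm_mean") "mean" else "mode",
                    fishers = if (method == "imm_mode") fishers else NULL)
      }
      eval_matrix[[t]] <- evaluate_all_tasks(spec, eval_params, tasks, test_data, t)
    }
    per_seed[[s]] <- list(seed = seed, eval_matrix = eval_matrix,
                          final_row = eval_matrix[[n_tasks]],
                          avg_accuracy = average_accuracy(eval_matrix[[n_tasks]]),
                          forgetting = task1_forgetting(eval_matrix),
                          history = do.call(rbind, histories),
                          curves = if (track_curves) do.call(rbind, curves) else NULL,
                          params = params)
  }
  final_rows <- do.call(rbind, lapply(per_seed, `[[`, "final_row"))
  structure(list(algorithm = algorithm, method = method, seeds = seeds,
                 per_seed = per_seed,
                 mean_final_row = colMeans(final_rows),
                 avg_accuracy = mean(vapply(per_seed, `[[`, numeric(1), "avg_accuracy")),
                 forgetting = mean(vapply(per_seed, `[[`, numeric(1), "forgetting"))),
            class = "pcnet_incremental")
}

#' @export
print.pcnet_incremental <- function(x, ...) {
  cat("pcnet incremental run: ", toupper(x$algorithm), "-", x$method,
      ", ", length(x$per_seed), " seed(s)\n", sep = "")
  cat("  final per-task accuracy (%):",
      paste(sprintf("%.2f", round_half_up(x$mean_final_row)), collapse = " "), "\n")
  cat(sprintf("  average %.2f | task-1 forgetting %.2f\n",
              round_half_up(x$avg_accuracy), round_half_up(x$forgetting)))
  invisible(x)
}
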