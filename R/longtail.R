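# Long-tailed recognition: exponential class-imbalance profile and training
# under the six classification objectives, each usable by backpropagation
# directly and by predictive coding through the output-error coupling.

#' Exponential class-count profile
#'
#' Per-class sample counts `N_l = N_max * gamma^{-(l-1)/(L_c-1)}` for classes
#' `l = 1..L_c`, where `gamma = N_max / N_min` is the imbalance ratio. Counts
#' are rounded to the nearest integer (half up) with a minimum of 1; the
#' endpoint ratio `N_1 / N_{L_c}` equals `gamma` exactly before rounding.
#'
#' @param N_max Count of the largest (head) class.
#' @param gamma Imbalance ratio (>= 1).
#' @param L_c Number of classes (>= 2).
#' @return A `pcnet_count_profile`: integer `counts`, `raw` (unrounded),
#'   `gamma`, `N_max`.
#' @export
longtail_counts <- function(N_max, gamma, L_c) {
  if (gamma < 1) stop("longtail_counts: gamma must be >= 1")
  stopifnot(N_max >= 1, L_c >= 2)
  l <- seq_len(L_c)
  raw <- N_max * gamma^(-(l - 1) / (L_c - 1))
  counts <- pmax(1L, as.integer(round_half_up(raw, 0)))
  structure(list(counts = counts, raw = raw, gamma = gamma, N_max = N_max,
                 L_c = as.integer(L_c)),
            class = "pcnet_count_profile")
}

#' @export
print.pcnet_count_profile <- function(x, ...) {
  cat("pcnet class-count profile: gamma =", x$gamma, ", N_max =", x$N_max, "\n")
  print(x$counts)
  invisible(x)
}

#' Subsample a balanced dataset to an imbalance profile
#'
#' Seeded uniform per-class subsampling to the profile's counts; intended for
#' the training split only (test sets stay balanced for unbiased evaluation).
#'
#' @param data A dataset (`x`, `y`, `n_classes`).
#' @param profile A `pcnet_count_profile` with `L_c == n_classes`.
#' @param seed Integer seed.
#' @return The imbalanced dataset, with the profile attached as `counts`.
#' @export
subsample_to_profile <- function(data, profile, seed = 1L) {
  stopifnot(inherits(profile, "pcnet_count_profile"),
            profile$L_c == data$n_classes)
  set.seed(seed)
  keep <- integer(0)
  for (cl in seq_len(data$n_classes)) {
    pool <- which(data$y == cl)
    want <- profile$counts[cl]
    if (length(pool) < want)
      stop("subsample_to_profile: class ", cl, " has ", length(pool),
           " samples but the profile requires ", want)
    keep <- c(keep, if (length(pool) > want) sort(sample(pool, want)) else pool)
  }
  list(x = data$x[keep, , drop = FALSE], y = data$y[keep],
       n_classes = data$n_classes, image_shape = data$image_shape,
       counts = profile$counts, indices = keep)
}

#' Default long-tailed training configuration
#'
#' Batch size 128, 100 epochs, weight decay 2e-4; predictive coding uses
#' weight learning rate 0.002, inference rate 0.1, 20 iterations under the
#' fixed prediction assumption. The BP learning rate is selected from a
#' five-fold growing grid starting at 1e-4 (best test performance kept).
#'
#' @param algorithm `"bp"` or `"pc"`.
#' @param ... Overrides.
#' @export
longtail_config <- function(algorithm = "bp", ...) {
  cfg <- list(batch_size = 128L, epochs = 100L, weight_decay = 2e-4,
              lr = if (algorithm == "pc") 0.002 else 0.0125,
              bp_lr_grid = 1e-4 * 5^(0:4),
              eta_v = 0.1, pc_iters = 20L, fixed_predictions = TRUE,
              gamma_f = 2, cb_beta = 0.999, ldam_C = 0.5, mixup_alpha = 1,
              dropout_rate = 0.5)
  utils::modifyList(cfg, list(...))
}

#' Train on long-tailed data and report balanced test accuracy
#'
#' Trains with the chosen objective — coupled into the predictive coding
#' output node or used directly under backpropagation — and reports overall
#' and per-class accuracy on the balanced test set (the per-class breakdown is
#' the classification-bias diagnostic).
#'
#' @param spec Network (e.g. [make_mlp3()] with dropout).
#' @param train_data Imbalanced training set from [subsample_to_profile()]
#'   (must carry `counts` for the count-aware objectives).
#' @param test_data Balanced test set.
#' @param objective One of `ce`, `mixup`, `focal`, `cb_focal`, `ldam`,
#'   `balanced_softmax`.
#' @param algorithm `"bp"` or `"pc"`.
#' @param config From [longtail_config()].
#' @param seed Integer seed.
#' @return `list(overall, per_class, params, history)`; accuracies in percent.
#' @export
train_longtail <- function(spec, train_data, test_data,
                           objective = c("ce", "mixup", "focal", "cb_focal",
                                         "ldam", "balanced_softmax"),
                           algorithm = c("bp", "pc"),
                           config = longtail_config(algorithm), seed = 1L) {
  objective <- match.arg(objective)
  algorithm <- match.arg(algorithm)
  counts <- train_data$counts
  if (objective %in% c("cb_focal", "ldam", "balanced_softmax") && is.null(counts))
    stop("objective '", objective, "' requires per-class counts on the training data")
  obj_name <- switch(objective,
                     ce = "cross_entropy", mixup = "cross_entropy",
                     focal = "focal", cb_focal = "cb_focal", ldam = "ldam",
                     balanced_softmax = "balanced_softmax")
  obj_args <- switch(objective,
                     focal = list(gamma_f = config$gamma_f),
                     cb_focal = list(gamma_f = config$gamma_f, beta = config$cb_beta,
                                     counts = counts),
                     ldam = list(C_margin = config$ldam_C, counts = counts),
                     balanced_softmax = list(counts = counts),
                     list())
  fit <- sgd_train(spec, init_params(spec, seed),
                   train_data$x, train_data$y, train_data$n_classes,
                   algorithm = algorithm, objective = obj_name,
                   epochs = config$epochs, batch_size = config$batch_size,
                   lr = config$lr, eta_v = config$eta_v,
                   pc_iters = config$pc_iters,
                   fixed_predictions = config$fixed_predictions,
                   weight_decay = config$weight_decay, schedule = "none",
                   seed = derive_seed(seed, 17),
                   mixup_alpha = if (objective == "mixup") config$mixup_alpha else NULL,
                   objective_args = obj_args)
  pred <- predict_classes(spec, fit$params, test_data$x)
  per_class <- vapply(seq_len(test_data$n_classes), function(cl) {
    sel <- test_data$y == cl
    accuracy_pct(pred[sel], test_data$y[sel])
  }, numeric(1))
  list(overall = accuracy_pct(pred, test_data$y), per_class = per_class,
       params = fit$params, history = fit$history)
}
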