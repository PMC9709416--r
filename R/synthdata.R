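# Deterministic synthetic image-classification generator. Class templates are
# low-frequency random fields (seeded white noise on a coarse grid, bilinearly
# upsampled), so both dense and convolutional architectures see spatial
# structure; samples are templates plus additive Gaussian noise. Everything is
# bit-identical under a fixed seed.

#' Generate a bank of class templates
#'
#' Draws `C` smooth random image templates with an enforced minimum pairwise
#' Euclidean distance (violating templates are redrawn). Templates are scaled
#' to unit root-mean-square amplitude.
#'
#' @param C Number of classes (>= 2).
#' @param image_shape Integer `c(H, W, channels)`.
#' @param seed Integer seed; the same `(C, shape, seed)` reproduces the bank
#'   bit-identically.
#' @param min_separation Minimum pairwise distance between templates
#'   (default 1, in units of per-template RMS 1).
#' @param coarse Coarse grid side for the low-frequency field (default 4).
#' @param max_tries Redraw budget before giving up.
#' @return A `pcnet_templates` object: `templates` (C x d matrix), shape, seed.
#' @export
make_templates <- function(C, image_shape, seed = 1L, min_separation = 1,
                           coarse = 4L, max_tries = 200L) {
  if (C < 2) stop("make_templates: need at least 2 classes")
  stopifnot(length(image_shape) == 3)
  set.seed(seed)
  H <- image_shape[1]; W <- image_shape[2]; ch <- image_shape[3]
  d <- H * W * ch
  draw <- function() {
    tpl <- numeric(0)
    for (cc in seq_len(ch)) {
      coarse_field <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
      tpl <- c(tpl, as.vector(bilinear_upsample(coarse_field, H, W)))
    }
    tpl / sqrt(mean(tpl^2))
  }
  templates <- matrix(0, C, d)
  for (i in seq_len(C)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      cand <- draw()
      if (i == 1 || min(sqrt(rowSums(sweep(templates[seq_len(i - 1L), , drop = FALSE],
                                           2L, cand)^2))) >= min_separation) {
        templates[i, ] <- cand; ok <- TRUE; break
      }
    }
    if (!ok) stop("make_templates: could not achieve min_separation ",
                  min_separation, " for class ", i)
  }
  structure(list(templates = templates, image_shape = as.integer(image_shape),
                 C = as.integer(C), seed = as.integer(seed),
                 min_separation = min_separation),
            class = "pcnet_templates")
}

# Bilinear upsample of a coarse matrix to H x W.
bilinear_upsample <- function(m, H, W) {
  ch <- nrow(m); cw <- ncol(m)
  ys <- seq(1, ch, length.out = H)
  xs <- seq(1, cw, length.out = W)
  y0 <- pmin(floor(ys), ch - 1L); x0 <- pmin(floor(xs), cw - 1L)
  fy <- ys - y0; fx <- xs - x0
  out <- matrix(0, H, W)
  for (j in seq_len(W)) {
    a <- m[y0, x0[j]] * (1 - fy) + m[y0 + 1, x0[j]] * fy
    b <- m[y0, x0[j] + 1] * (1 - fy) + m[y0 + 1, x0[j] + 1] * fy
    out[, j] <- a * (1 - fx[j]) + b * fx[j]
  }
  out
}

#' Sample a labeled dataset from a template bank
#'
#' Each item is its class template plus i.i.d. Gaussian noise of standard
#' deviation `sigma`; label = class index (1-based).
#'
#' @param bank A `pcnet_templates` bank.
#' @param counts Per-class sample counts (length `bank$C`, nonnegative).
#' @param sigma Additive noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return `list(x, y, n_classes, image_shape)` with `x` an n x d matrix and
#'   `y` integer labels.
#' @export
sample_dataset <- function(bank, counts, sigma, seed = 1L) {
  stopifnot(inherits(bank, "pcnet_templates"), length(counts) == bank$C)
  if (any(counts < 0)) stop("sample_dataset: negative counts")
  set.seed(seed)
  n <- sum(counts)
  d <- ncol(bank$templates)
  x <- matrix(0, n, d)
  y <- integer(n)
  row <- 0L
  for (cl in seq_len(bank$C)) {
    if (counts[cl] == 0) next
    idx <- row + seq_len(counts[cl])
    x[idx, ] <- matrix(bank$templates[cl, ], counts[cl], d, byrow = TRUE) +
      if (sigma > 0) matrix(stats::rnorm(counts[cl] * d, sd = sigma), counts[cl], d) else 0
    y[idx] <- cl
    row <- row + as.integer(counts[cl])
  }
  list(x = x, y = y, n_classes = bank$C, image_shape = bank$image_shape)
}

#' Nearest-template classification accuracy
#'
#' Classifies each sample by the closest template (the generator's own oracle
#' classifier); used to calibrate noise levels to a target difficulty.
#'
#' @param bank A `pcnet_templates` bank.
#' @param data A dataset from [sample_dataset()].
#' @return Accuracy in percent.
#' @export
nearest_template_accuracy <- function(bank, data) {
  tpl <- bank$templates
  d2 <- outer(rowSums(data$x^2), rowSums(tpl^2), `+`) - 2 * data$x %*% t(tpl)
  accuracy_pct(max.col(-d2, ties.method = "first"), data$y)
}

#' Few-shot class bank of synthetic characters
#'
#' A large set of low-shot classes: `C_chars` templates with `variants` noisy
#' realizations each, emulating a handwritten-character bank at small scale.
#'
#' @param C_chars Number of character classes.
#' @param variants Items per class.
#' @param image_shape Integer `c(H, W, channels)`.
#' @param sigma Within-class noise standard deviation.
#' @param seed Integer seed.
#' @param min_separation Passed to [make_templates()].
#' @return `list(x, y, n_classes, image_shape, templates)`.
#' @export
make_fewshot_bank <- function(C_chars, variants, image_shape, sigma, seed = 1L,
                              min_separation = 1) {
  bank <- make_templates(C_chars, image_shape, seed = seed,
                         min_separation = min_separation)
  data <- sample_dataset(bank, rep(variants, C_chars), sigma,
                         seed = derive_seed(seed, 1L))
  data$templates <- bank
  data
}

#' Split a class bank into disjoint train/test class partitions
#'
#' @param bank A bank from [make_fewshot_bank()].
#' @param train_fraction Fraction of classes assigned to training.
#' @param seed Integer seed for the class permutation.
#' @return `list(train, test)` of banks over disjoint class sets (labels are
#'   re-indexed 1..k within each split).
#' @export
split_bank_classes <- function(bank, train_fraction = 0.6, seed = 1L) {
  set.seed(seed)
  cls <- sample(bank$n_classes)
  ntr <- floor(bank$n_classes * train_fraction)
  take <- function(keep) {
    sel <- bank$y %in% keep
    relab <- match(bank$y[sel], keep)
    list(x = bank$x[sel, , drop = FALSE], y = relab, n_classes = length(keep),
         image_shape = bank$image_shape)
  }
  list(train = take(cls[seq_len(ntr)]), test = take(cls[(ntr + 1L):bank$n_classes]))
}

#' Difficulty report: oracle accuracy versus noise level
#'
#' Tabulates nearest-template accuracy across a grid of noise standard
#' deviations, for choosing a noise level with a target Bayes-style difficulty.
#'
#' @param bank A `pcnet_templates` bank.
#' @param sigma_grid Numeric vector of noise levels.
#' @param n_per_class Samples per class per level.
#' @param seed Integer seed.
#' @return A data frame with columns `sigma` and `accuracy` (percent).
#' @export
difficulty_report <- function(bank, sigma_grid, n_per_class = 50L, seed = 1L) {
  acc <- vapply(seq_along(sigma_grid), function(i) {
    data <- sample_dataset(bank, rep(n_per_class, bank$C), sigma_grid[i],
                           seed = derive_seed(seed, i))
    nearest_template_accuracy(bank, data)
  }, numeric(1))
  data.frame(sigma = sigma_grid, accuracy = acc)
}
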