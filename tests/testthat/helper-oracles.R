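# Shared fixtures and independent oracles for the test suite.

# A seeded random sequential MLP with ReLU hidden layers and identity output.
random_mlp <- function(seed, max_units = 32L, n_layers = NULL) {
  set.seed(seed)
  L <- if (is.null(n_layers)) sample(2:3, 1) else n_layers
  widths <- sample(2:max_units, L + 1L, replace = TRUE)
  layers <- lapply(seq_len(L), function(i)
    layer_affine(widths[i], widths[i + 1L], if (i < L) "relu" else "identity"))
  network_spec(layers, widths[1])
}

random_batch <- function(spec, n = 4L, seed = 1L) {
  set.seed(seed)
  list(x = matrix(stats::rnorm(n * spec$input_dim), n),
       y = one_hot(sample(spec$output_dim, n, replace = TRUE), spec$output_dim))
}

# Central finite differences of the objective loss with respect to every
# parameter (descent-direction convention, matching bp_gradient). The
# independent oracle for all analytic gradients.
fd_gradient <- function(spec, params, x, y, objective, eps = 1e-5,
                        max_per_param = 12L, ...) {
  loss_at <- function(p) {
    st <- forward_pass(spec, p, x)
    objective_eval(st$vhat[[spec$n_layers]], y, objective, ...)$loss
  }
  g <- list()
  for (i in seq_along(params)) {
    gi <- list()
    for (nm in names(params[[i]])) {
      th <- params[[i]][[nm]]
      idx <- unique(round(seq(1, length(th), length.out = min(max_per_param, length(th)))))
      vals <- rep(NA_real_, length(th))
      for (j in idx) {
        p1 <- params; p1[[i]][[nm]][j] <- th[j] + eps
        p2 <- params; p2[[i]][[nm]][j] <- th[j] - eps
        vals[j] <- -(loss_at(p1) - loss_at(p2)) / (2 * eps)
      }
      gi[[nm]] <- vals
    }
    g[[i]] <- gi
  }
  g
}

# Max relative error between an analytic gradient set and the (partial)
# finite-difference oracle, over the probed coordinates.
fd_max_rel_err <- function(grads, fd) {
  worst <- 0
  for (i in seq_along(grads)) for (nm in names(grads[[i]])) {
    a <- as.vector(grads[[i]][[nm]])
    b <- fd[[i]][[nm]]
    sel <- !is.na(b)
    if (!any(sel)) next
    worst <- max(worst, max(abs(a[sel] - b[sel])) / max(abs(b[sel]), 1e-8))
  }
  worst
}

# Small synthetic classification world shared by the pipeline tests.
toy_world <- function(n_classes = 10L, train_per_class = 200L,
                      test_per_class = 50L, sigma = 4, seed = 101L) {
  bank <- make_templates(n_classes, c(8L, 8L, 1L), seed = seed)
  list(bank = bank,
       train = sample_dataset(bank, rep(train_per_class, n_classes), sigma,
                              seed = derive_seed(seed, 1)),
       test = sample_dataset(bank, rep(test_per_class, n_classes), sigma,
                             seed = derive_seed(seed, 2)))
}
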