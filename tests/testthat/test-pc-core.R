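test_that("forward pass computes predictions layer by layer and starts at zero energy", {
  # identity chain: predictions equal the input at every layer
  spec <- network_spec(list(layer_affine(3, 3, "identity"),
                            layer_affine(3, 3, "identity")), 3)
  params <- list(list(W = diag(3), b = rep(0, 3)), list(W = diag(3), b = rep(0, 3)))
  x <- matrix(c(1, 2, 3), 1)
  st <- forward_pass(spec, params, x)
  expect_equal(st$vhat[[1]], x)
  expect_equal(st$vhat[[2]], x)
  expect_equal(free_energy(st), 0)

  # single affine layer, weight 2, bias 0, relu: f([3]) = [6]
  spec1 <- network_spec(list(layer_affine(1, 1, "relu")), 1)
  p1 <- list(list(W = matrix(2), b = 0))
  expect_equal(forward_pass(spec1, p1, matrix(3))$vhat[[1]], matrix(6))

  # any state straight out of the forward pass has F = 0
  spec2 <- random_mlp(5)
  b <- random_batch(spec2, seed = 6)
  expect_equal(free_energy(forward_pass(spec2, init_params(spec2, 1), b$x)), 0)

  # shape mismatch names the problem
  expect_error(forward_pass(spec1, p1, matrix(c(1, 2), 1)), "input width")
})

test_that("clamping the target sets the output error with the prediction-minus-target sign", {
  # f(x) = 2x, x = 1, y = 5: e_1 = 2 - 5 = -3
  spec <- network_spec(list(layer_affine(1, 1, "identity")), 1)
  p <- list(list(W = matrix(2), b = 0))
  st <- clamp_target(forward_pass(spec, p, matrix(1)), matrix(5))
  expect_equal(st$e[[1]], matrix(-3))
  expect_true(st$clamped)
  expect_equal(st$v[[2]], matrix(5))

  # target equal to the prediction gives zero error; clamping is idempotent
  st0 <- forward_pass(spec, p, matrix(1))
  st1 <- clamp_target(st0, matrix(2))
  expect_equal(st1$e[[1]], matrix(0))
  expect_identical(clamp_target(st1, matrix(2)), st1)

  expect_error(clamp_target(st0, matrix(c(1, 2), 1)), "shape")
})

test_that("free energy is half the summed squared errors, batch-averaged, nonnegative", {
  st <- structure(list(e = list(matrix(c(1, 2), 1), matrix(3)), n = 1),
                  class = "pcnet_state")
  expect_equal(free_energy(st), 7)  # (1 + 4 + 9) / 2
  st$n <- 2
  expect_equal(free_energy(st), 3.5)
  for (s in 1:5) {
    spec <- random_mlp(s)
    b <- random_batch(spec, seed = s)
    st2 <- clamp_target(forward_pass(spec, init_params(spec, s), b$x), b$y)
    expect_gte(free_energy(st2), 0)
  }
})

test_that("one inference step reproduces the hand-computed activation update", {
  # two-layer scalar linear chain: v1 <- v1 + eta * (e1 - w2 * e2)
  w1 <- 1.5; w2 <- -0.8; x <- 2; y <- 1; eta <- 0.1
  spec <- network_spec(list(layer_affine(1, 1, "identity"),
                            layer_affine(1, 1, "identity")), 1)
  p <- list(list(W = matrix(w1), b = 0), list(W = matrix(w2), b = 0))
  st <- clamp_target(forward_pass(spec, p, matrix(x)), matrix(y))
  v1hat <- w1 * x; v2hat <- w2 * v1hat
  e1 <- 0; e2 <- v2hat - y
  v1_new <- v1hat + eta * (e1 - w2 * e2)
  st2 <- inference_step(st, spec, p, eta_v = eta)
  expect_equal(st2$v[[2]], matrix(v1_new))
  expect_equal(st2$e[[1]], matrix(v1hat - v1_new))

  # all-zero errors are a fixed point
  st0 <- clamp_target(forward_pass(spec, p, matrix(x)), matrix(v2hat))
  st0b <- inference_step(st0, spec, p, eta_v = eta)
  expect_equal(st0b$v, st0$v)
  expect_equal(attr(st0b, "dv_max"), 0)
})

test_that("fixed-prediction equilibrium errors equal backpropagation deltas", {
  for (s in 1:10) {
    spec <- random_mlp(s)
    params <- init_params(spec, s + 100)
    b <- random_batch(spec, seed = s + 200)
    st <- clamp_target(forward_pass(spec, params, b$x), b$y)
    inf <- run_inference(st, spec, params, eta_v = 1, max_iters = 500L, tol = 1e-10)
    expect_true(inf$converged)
    # oracle: chain-rule deltas, computed independently layer by layer
    L <- spec$n_layers
    delta <- st$vhat[[L]] - b$y
    for (i in rev(seq_len(L))) {
      expect_lt(max(abs(inf$state$e[[i]] - delta)) / max(abs(delta), 1e-12), 1e-6)
      if (i > 1) delta <- pcnet:::layer_jtv(spec$layers[[i]], params[[i]],
                                            st$ctx[[i]], delta)
    }
  }
})

test_that("run_inference honours the iteration contract and detects divergence", {
  spec <- random_mlp(3)
  params <- init_params(spec, 3)
  b <- random_batch(spec, seed = 3)
  st <- clamp_target(forward_pass(spec, params, b$x), b$y)
  r <- run_inference(st, spec, params, eta_v = 0.1, max_iters = 20L, tol = 0)
  expect_length(r$trace, 20L)
  expect_false(r$converged)

  # target equal to prediction: converges immediately, F stays 0
  st0 <- clamp_target(forward_pass(spec, params, b$x),
                      forward_pass(spec, params, b$x)$vhat[[spec$n_layers]])
  r0 <- run_inference(st0, spec, params, tol = 1e-12)
  expect_true(r0$converged)
  expect_equal(r0$trace, 0)

  expect_error(run_inference(st, spec, params, eta_v = 5, max_iters = 200L,
                             explosion = 10),
               "diverged")
})

test_that("free energy is non-increasing under re-evaluated predictions", {
  worst <- 0
  for (s in 1:30) {
    spec <- random_mlp(s, n_layers = 3)
    params <- init_params(spec, s)
    b <- random_batch(spec, seed = s + 50)
    st <- clamp_target(forward_pass(spec, params, b$x), b$y)
    r <- run_inference(st, spec, params, eta_v = 0.1, max_iters = 20L,
                       fixed_predictions = FALSE)
    tr <- c(free_energy(st), r$trace)
    worst <- max(worst, max(diff(tr)))
    expect_true(all(tr >= 0))
  }
  expect_lte(worst, 1e-10)
})

test_that("the weight rule is local: distant errors never move a layer's gradient", {
  spec <- random_mlp(11, n_layers = 3)
  params <- init_params(spec, 11)
  b <- random_batch(spec, seed = 11)
  st <- clamp_target(forward_pass(spec, params, b$x), b$y)
  st <- run_inference(st, spec, params, max_iters = 5L)$state
  g0 <- weight_gradient(st, spec, params)
  for (i in 1:3) {
    st2 <- st
    for (j in setdiff(1:3, i)) st2$e[[j]] <- st2$e[[j]] + 100
    g1 <- weight_gradient(st2, spec, params)
    expect_identical(g1[[i]], g0[[i]])
  }
  # all-zero errors give all-zero gradients
  stz <- st
  for (j in 1:3) stz$e[[j]] <- stz$e[[j]] * 0
  expect_true(all(unlist(weight_gradient(stz, spec, params)) == 0))
})

test_that("single-layer weight gradient equals the negative loss gradient (finite differences)", {
  spec <- network_spec(list(layer_affine(3, 2, "identity")), 3)
  params <- init_params(spec, 4)
  set.seed(4)
  x <- matrix(rnorm(6), 2)
  y <- matrix(rnorm(4), 2)
  st <- clamp_target(forward_pass(spec, params, x), y)
  g <- weight_gradient(st, spec, params)
  fd <- fd_gradient(spec, params, x, y, "squared_error")
  expect_lt(fd_max_rel_err(g, fd), 1e-6)
})

test_that("apply_update performs theta + eta * dtheta with optional decay", {
  params <- list(list(W = matrix(1), b = 0.5))
  grads <- structure(list(list(W = matrix(0.5), b = 0)), class = "pcnet_grads")
  expect_equal(apply_update(params, grads, 0.1)[[1]]$W, matrix(1.05))
  expect_equal(apply_update(params, grads, 0)[[1]]$W, matrix(1))
  zero <- structure(list(list(W = matrix(0), b = 0)), class = "pcnet_grads")
  expect_equal(apply_update(params, zero, 0.1), params)
  # decay shrinks weights, not biases
  upd <- apply_update(params, zero, 0.1, weight_decay = 0.5)
  expect_equal(upd[[1]]$W, matrix(0.95))
  expect_equal(upd[[1]]$b, 0.5)
})

test_that("a perfect prediction is a fixed point with zero gradients", {
  spec <- random_mlp(21)
  params <- init_params(spec, 21)
  b <- random_batch(spec, seed = 21)
  yhat <- forward_pass(spec, params, b$x)$vhat[[spec$n_layers]]
  st <- clamp_target(forward_pass(spec, params, b$x), yhat)
  st2 <- inference_step(st, spec, params)
  expect_equal(st2$v, st$v)
  expect_true(all(unlist(weight_gradient(st2, spec, params)) == 0))
  expect_true(all(unlist(bp_gradient(spec, params, b$x, yhat)) == 0))
})

test_that("bp_gradient matches finite differences and the PC equilibrium gradient", {
  for (s in c(31, 32)) {
    spec <- random_mlp(s)
    params <- init_params(spec, s)
    b <- random_batch(spec, seed = s)
    for (obj in c("squared_error", "cross_entropy")) {
      g <- bp_gradient(spec, params, b$x, b$y, obj)
      expect_lt(fd_max_rel_err(g, fd_gradient(spec, params, b$x, b$y, obj)), 1e-5)
      pcg <- pc_gradient(spec, params, b$x, b$y, obj, eta_v = 1,
                         max_iters = 500L, tol = 1e-10)
      expect_lt(max_rel_err(pcg$grads, g), 1e-6)
    }
  }
})

test_that("equivalence extends to conv blocks with batch normalization", {
  l1 <- layer_conv_block(c(6, 6, 2), 4, batchnorm = TRUE)
  spec <- network_spec(list(l1, layer_affine(l1$d_out, 3, "identity")), 72)
  params <- init_params(spec, 9)
  set.seed(9)
  x <- matrix(rnorm(4 * 72), 4)
  y <- one_hot(c(1, 2, 3, 1), 3)
  g <- bp_gradient(spec, params, x, y, "cross_entropy")
  expect_lt(fd_max_rel_err(g, fd_gradient(spec, params, x, y, "cross_entropy")), 1e-5)
  pcg <- pc_gradient(spec, params, x, y, "cross_entropy", eta_v = 1,
                     max_iters = 100L, tol = 1e-10)
  expect_lt(max_rel_err(pcg$grads, g), 1e-6)
})

test_that("checkpoints round-trip bit-exactly", {
  spec <- random_mlp(41)
  params <- init_params(spec, 41)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(params, f)
  expect_identical(load_checkpoint(f), params)
  unlink(f)
})
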