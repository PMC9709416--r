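test_that("episode sampling respects counts, disjointness, and the seed", {
  bank <- make_fewshot_bank(12, 8, c(8, 8, 1), sigma = 1, seed = 1)
  e <- sample_episode(bank, N = 5, k = 1, q = 1, seed = 2)
  expect_length(e$support_idx, 5L)
  expect_length(e$query_idx, 5L)
  expect_length(intersect(e$support_idx, e$query_idx), 0L)
  expect_identical(sample_episode(bank, 5, 1, 1, seed = 2), e)
  e2 <- sample_episode(bank, 4, 2, 3, seed = 3)
  expect_equal(as.vector(table(e2$support_y)), rep(2L, 4))
  expect_equal(as.vector(table(e2$query_y)), rep(3L, 4))
  expect_error(sample_episode(bank, 13, 1, 1, seed = 1), "classes")
  expect_error(sample_episode(bank, 3, 5, 5, seed = 1), "items")
})

test_that("prototypes are class means with the expected invariances", {
  set.seed(3)
  emb <- matrix(rnorm(12), 4)
  # k = 1: the prototype is the single support embedding
  expect_equal(compute_prototypes(emb[1, , drop = FALSE], 1L, 1L), emb[1, , drop = FALSE])
  # duplicated support items leave the prototype unchanged
  expect_equal(compute_prototypes(rbind(emb[1, ], emb[1, ]), c(1L, 1L), 1L),
               emb[1, , drop = FALSE])
  # two supports at +/- u average to the origin
  expect_equal(compute_prototypes(rbind(emb[2, ], -emb[2, ]), c(1L, 1L), 1L),
               matrix(0, 1, 3))
  # permutation invariance in the support set
  labs <- c(1L, 2L, 1L, 2L)
  perm <- c(3L, 2L, 4L, 1L)
  expect_equal(compute_prototypes(emb, labs, 2L),
               compute_prototypes(emb[perm, ], labs[perm], 2L))
})

test_that("episode scores are negative squared distances with softmax symmetry", {
  proto <- rbind(c(0, 0), c(4, 0), c(0, 4))
  q <- rbind(c(0, 0), c(2, 0))
  lg <- episode_logits(q, proto)
  p <- pcnet:::softmax_rows(lg)
  expect_gt(p[1, 1], 0.999)            # query on a prototype
  expect_equal(p[2, 1], p[2, 2])       # equidistant query: symmetric scores
  # translation invariance
  shift <- matrix(c(3, -2), 2, 2, byrow = TRUE)
  lg2 <- episode_logits(q + shift[, 1:2], sweep(proto, 2, c(-3, 2), `-`))
  expect_equal(pcnet:::softmax_rows(lg2), p)
})

test_that("the episode loss gradient matches finite differences", {
  set.seed(4)
  emb_s <- matrix(rnorm(6 * 3), 6)
  emb_q <- matrix(rnorm(4 * 3), 4)
  sy <- rep(1:3, each = 2); qy <- c(1L, 2L, 3L, 1L)
  pl <- pcnet:::proto_loss_grad(emb_s, emb_q, sy, qy, 3L, 2L)
  eps <- 1e-6
  for (j in seq_len(length(emb_s))) {
    e1 <- emb_s; e1[j] <- e1[j] + eps
    e2 <- emb_s; e2[j] <- e2[j] - eps
    fd <- (pcnet:::proto_loss_grad(e1, emb_q, sy, qy, 3L, 2L)$loss -
           pcnet:::proto_loss_grad(e2, emb_q, sy, qy, 3L, 2L)$loss) / (2 * eps)
    expect_lt(abs(fd - pl$g_support[j]), 1e-6)
  }
  for (j in seq_len(length(emb_q))) {
    e1 <- emb_q; e1[j] <- e1[j] + eps
    e2 <- emb_q; e2[j] <- e2[j] - eps
    fd <- (pcnet:::proto_loss_grad(emb_s, e1, sy, qy, 3L, 2L)$loss -
           pcnet:::proto_loss_grad(emb_s, e2, sy, qy, 3L, 2L)$loss) / (2 * eps)
    expect_lt(abs(fd - pl$g_query[j]), 1e-6)
  }
})

test_that("a noise-free bank with an identity encoder is solved exactly", {
  bank <- make_fewshot_bank(8, 6, c(6, 6, 1), sigma = 0, seed = 5)
  spec <- network_spec(list(layer_affine(36, 36, "identity")), 36)
  params <- list(list(W = diag(36), b = rep(0, 36)))
  r <- evaluate_fewshot(spec, params, bank, N = 5, k = 1, q = 2,
                        episodes = 50, seed = 6)
  expect_equal(r$mean, 100)
})

test_that("the episodic evaluator is calibrated at chance on label-free banks", {
  spec <- make_protonet4(c(16, 16, 1))
  params <- init_params(spec, 1)
  for (N in c(5L, 20L)) {
    r <- fewshot_null_calibration(spec, params, N, n_banks = 8L,
                                  episodes_per_bank = 40L, seed = 2)
    expect_lt(abs(r$mean - r$chance), 3 * r$se)
  }
})

test_that("accuracy falls with more ways and rises with more shots", {
  bank <- make_fewshot_bank(40, 20, c(16, 16, 1), sigma = 2, seed = 101)
  spec <- make_protonet4(c(16, 16, 1))
  params <- init_params(spec, 1)
  acc <- sapply(c(5, 10, 20, 30), function(N) sapply(c(1, 5), function(k)
    evaluate_fewshot(spec, params, bank, N, k, q = 15, episodes = 150,
                     seed = 12)$mean))
  expect_true(all(diff(acc[1, ]) <= 0))   # k = 1 row, non-increasing in N
  expect_true(all(diff(acc[2, ]) <= 0))   # k = 5 row
  expect_true(all(acc[2, ] >= acc[1, ]))  # more shots never hurt
})

test_that("episodic training improves the encoder, similarly for both algorithms", {
  bank <- make_fewshot_bank(40, 20, c(16, 16, 1), sigma = 3, seed = 101)
  sp <- split_bank_classes(bank, 0.6, seed = 5)
  spec <- make_protonet4(c(16, 16, 1))
  untrained <- evaluate_fewshot(spec, init_params(spec, 2), sp$test, 5, 1,
                                q = 15, episodes = 200, seed = 7)$mean
  accs <- c()
  for (alg in c("bp", "pc")) {
    cfg <- fewshot_config(alg, epochs = 4L, episodes_per_epoch = 15L,
                          lr = 0.01, train_q = 5L)
    fit <- train_fewshot(spec, sp$train, alg, cfg, seed = 2)
    acc <- evaluate_fewshot(spec, fit$params, sp$test, 5, 1, q = 15,
                            episodes = 200, seed = 7)$mean
    expect_gt(acc, untrained + 3)  # clear improvement on held-out classes
    accs <- c(accs, acc)
  }
  expect_lt(abs(accs[1] - accs[2]), 10)  # the two algorithms land close together
})
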