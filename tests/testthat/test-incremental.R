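test_that("task sequences partition the label set per scheme", {
  world <- toy_world(train_per_class = 20L, test_per_class = 10L)
  disj <- build_task_sequence(world$train$y, world$test$y, "disjoint")
  expect_length(disj, 2L)
  expect_equal(disj[[1]]$classes, 1:5)
  expect_equal(disj[[2]]$classes, 6:10)
  spl <- build_task_sequence(world$train$y, world$test$y, "split")
  expect_length(spl, 5L)
  expect_equal(spl[[3]]$classes, 5:6)
  # every split task holds exactly 2 classes x 20 training items
  expect_true(all(vapply(spl, function(t) length(t$train_idx), integer(1)) == 40L))
  # class sets are pairwise disjoint and cover the label set
  expect_equal(sort(unlist(lapply(spl, `[[`, "classes"))), 1:10)
  # subsampling quota caps per-class training counts reproducibly
  q <- build_task_sequence(world$train$y, world$test$y, "split", seed = 3,
                           per_class_quota = 5L)
  expect_true(all(vapply(q, function(t) length(t$train_idx), integer(1)) == 10L))
  expect_identical(build_task_sequence(world$train$y, world$test$y, "split",
                                       seed = 3, per_class_quota = 5L), q)
  expect_error(build_task_sequence(rep(1:3, 5), rep(1:3, 2), "split"),
               "not divisible")
})

test_that("the plateau schedule divides by 3 after 5 flat epochs and floors at 1e-4", {
  s <- plateau_state(0.05)
  for (l in c(1, 0.9, 0.8)) s <- plateau_schedule(s, l)  # improving: unchanged
  expect_equal(s$lr, 0.05)
  for (i in 1:5) s <- plateau_schedule(s, 0.8)           # five flat epochs
  expect_equal(s$lr, 0.05 / 3)
  expect_equal(s$counter, 0L)
  for (i in 1:200) s <- plateau_schedule(s, 0.8)
  expect_equal(s$lr, 1e-4)
})

test_that("average accuracy reproduces the printed table arithmetic", {
  expect_equal(round_half_up(average_accuracy(c(99.89, 97.09, 99.28, 99.39, 98.37))),
               98.80)
  expect_equal(round_half_up(average_accuracy(c(75.68, 97.11))), 86.40)
  expect_equal(average_accuracy(rep(42.5, 4)), 42.5)
  expect_error(average_accuracy(numeric(0)), "empty")
})

test_that("evaluation rows have the contract length and sensible forced values", {
  world <- toy_world(train_per_class = 20L, test_per_class = 10L)
  tasks <- build_task_sequence(world$train$y, world$test$y, "split")
  spec <- make_mlp3(64, 8, 10)
  params <- init_params(spec, 1)
  row <- evaluate_all_tasks(spec, params, tasks, world$test, 3)
  expect_length(row, 3L)
  expect_true(all(row >= 0 & row <= 100))
  # a head that always scores class 1 highest gets 50% on a balanced 2-class task
  forced <- params
  forced[[3]]$W[] <- 0
  forced[[3]]$b <- c(10, rep(0, 9))
  expect_equal(evaluate_all_tasks(spec, forced, tasks, world$test, 1), 50)
})

test_that("EWC reduces to plain SGD at lambda 0 and is inert at the anchor", {
  spec <- make_mlp3(8, 6, 4)
  params <- init_params(spec, 2)
  grads <- structure(lapply(params, function(l) lapply(l, function(v) v * 0.1)),
                     class = "pcnet_grads")
  anchor <- list(params = params,
                 fisher = lapply(params, function(l) lapply(l, function(v) abs(v))))
  expect_identical(ewc_hook(list(anchor), 0)(grads, params), grads)
  # theta == theta*: the quadratic penalty contributes nothing
  expect_equal(ewc_hook(list(anchor), 50)(grads, params), grads)
  # away from the anchor the gradient is pulled back toward it
  shifted <- apply_update(params, grads, 1)
  pulled <- ewc_hook(list(anchor), 50)(grads, shifted)
  expect_false(isTRUE(all.equal(pulled, grads)))
  expect_error(ewc_hook(list(anchor), -1), "nonnegative")
})

test_that("moment-matching merges average snapshots and respect Fisher weighting", {
  spec <- make_mlp3(6, 4, 3)
  p1 <- init_params(spec, 1)
  expect_equal(imm_merge(list(p1, p1), "mean"), p1)
  neg <- lapply(p1, function(l) lapply(l, function(v) -v))
  merged <- imm_merge(list(p1, neg), "mean")
  expect_true(all(abs(unlist(merged)) < 1e-12))
  # one Fisher far larger than the other: merge approaches that snapshot
  p2 <- init_params(spec, 2)
  f_big <- lapply(p1, function(l) lapply(l, function(v) v * 0 + 1e8))
  f_small <- lapply(p1, function(l) lapply(l, function(v) v * 0 + 1))
  m <- imm_merge(list(p1, p2), "mode", fishers = list(f_big, f_small))
  expect_lt(max(abs(unlist(m) - unlist(p1))), 1e-6)
  expect_error(imm_merge(list(p1, init_params(make_mlp3(6, 5, 3), 1)), "mean"),
               "shape mismatch")
})

test_that("single-task training degenerates to ordinary supervised learning", {
  world <- toy_world(train_per_class = 40L, test_per_class = 20L, sigma = 2)
  tasks <- build_task_sequence(world$train$y, world$test$y, "disjoint")[1]
  class(tasks) <- "pcnet_tasks"
  spec <- make_mlp3(64, 32, 10)
  r <- train_sequential(spec, tasks, world$train, world$test, "bp", "sgd",
                        incremental_config("bp", epochs_per_task = 20L), seeds = 1)
  expect_length(r$per_seed[[1]]$eval_matrix, 1L)
  expect_length(r$per_seed[[1]]$eval_matrix[[1]], 1L)
  expect_gt(r$avg_accuracy, 60)  # well above the 20% five-way chance level
})

test_that("repeating an identical task does not degrade its accuracy", {
  world <- toy_world(train_per_class = 40L, test_per_class = 20L, sigma = 2)
  t1 <- build_task_sequence(world$train$y, world$test$y, "disjoint")[[1]]
  tasks <- structure(list(t1, t1), class = "pcnet_tasks")
  for (alg in c("bp", "pc")) {
    r <- train_sequential(make_mlp3(64, 32, 10), tasks, world$train, world$test,
                          alg, "sgd",
                          incremental_config(alg, epochs_per_task = 4L),
                          seeds = 1:2)
    drop <- mean(vapply(r$per_seed, function(ps)
      ps$eval_matrix[[1]][1] - ps$eval_matrix[[2]][1], numeric(1)))
    expect_lt(drop, 3)  # no forgetting beyond seed noise
  }
})

test_that("the just-trained task beats chance for both algorithms without backward transfer", {
  world <- toy_world()
  tasks <- build_task_sequence(world$train$y, world$test$y, "split")
  spec <- make_mlp3(64, 50, 10)
  for (alg in c("bp", "pc")) {
    r <- train_sequential(spec, tasks, world$train, world$test, alg, "sgd",
                          incremental_config(alg, epochs_per_task = 5L), seeds = 1:3)
    diag_acc <- sapply(r$per_seed, function(ps)
      vapply(seq_along(tasks), function(t) ps$eval_matrix[[t]][t], numeric(1)))
    expect_true(all(diag_acc > 65))  # chance is 50% on 2-class tasks
    # task-1 accuracy never improves systematically from later training; small
    # negative values are restricted-scoring noise, not real backward transfer
    expect_gt(r$forgetting, -15)
  }
})

test_that("strong consolidation trades new-task accuracy for old-task retention", {
  # moderate noise so task 1 converges: the Fisher is then informative and the
  # quadratic anchor stable at this strength
  world <- toy_world(train_per_class = 60L, test_per_class = 30L, sigma = 2)
  tasks <- build_task_sequence(world$train$y, world$test$y, "disjoint")
  spec <- make_mlp3(64, 50, 10)
  cfg_sgd <- incremental_config("bp", epochs_per_task = 8L)
  cfg_ewc <- incremental_config("bp", epochs_per_task = 8L, ewc_lambda = 50,
                                fisher_samples = 150L)
  r_sgd <- train_sequential(spec, tasks, world$train, world$test, "bp", "sgd",
                            cfg_sgd, seeds = 1:3)
  r_ewc <- train_sequential(spec, tasks, world$train, world$test, "bp", "ewc",
                            cfg_ewc, seeds = 1:3)
  task1_sgd <- mean(vapply(r_sgd$per_seed, function(p) p$final_row[1], numeric(1)))
  task1_ewc <- mean(vapply(r_ewc$per_seed, function(p) p$final_row[1], numeric(1)))
  task2_sgd <- mean(vapply(r_sgd$per_seed, function(p) p$final_row[2], numeric(1)))
  task2_ewc <- mean(vapply(r_ewc$per_seed, function(p) p$final_row[2], numeric(1)))
  expect_gt(task1_ewc, task1_sgd)
  expect_lt(task2_ewc, task2_sgd + 1e-9)
})

test_that("moment-matching methods run end to end on a short 2-task sequence", {
  world <- toy_world(train_per_class = 40L, test_per_class = 20L)
  tasks <- build_task_sequence(world$train$y, world$test$y, "disjoint")
  spec <- make_mlp3(64, 30, 10)
  for (m in c("imm_mean", "imm_mode")) {
    r <- train_sequential(spec, tasks, world$train, world$test, "bp", m,
                          incremental_config("bp", epochs_per_task = 4L,
                                             fisher_samples = 50L), seeds = 1)
    expect_length(r$mean_final_row, 2L)
    expect_true(all(r$mean_final_row >= 0 & r$mean_final_row <= 100))
  }
})
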