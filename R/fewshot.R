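# Episodic few-shot recognition with prototypical networks: N-way k-shot
# episodes, class-mean prototypes in embedding space, softmax over negative
# squared Euclidean distances, and episodic training of the encoder under
# either learning algorithm.

#' Sample an N-way k-shot episode
#'
#' Seeded sampling without replacement: N classes from the bank, then k
#' support and q query items per class (disjoint by construction).
#'
#' @param bank A class bank (`x`, `y`, `n_classes`).
#' @param N Ways (number of episode classes).
#' @param k Shots (support items per class).
#' @param q Queries per class (default 15).
#' @param seed Integer seed.
#' @return A `pcnet_episode`: support/query index vectors into the bank,
#'   episode labels 1..N, and the chosen classes.
#' @export
sample_episode <- function(bank, N, k, q = 15L, seed = 1L) {
  if (bank$n_classes < N)
    stop("sample_episode: bank has ", bank$n_classes, " classes, need ", N)
  set.seed(seed)
  classes <- sample(bank$n_classes, N)
  support_idx <- integer(0); query_idx <- integer(0)
  for (cl in classes) {
    pool <- which(bank$y == cl)
    if (length(pool) < k + q)
      stop("sample_episode: class ", cl, " has ", length(pool),
           " items, need ", k + q)
    pick <- sample(pool, k + q)
    support_idx <- c(support_idx, pick[seq_len(k)])
    query_idx <- c(query_idx, pick[k + seq_len(q)])
  }
  structure(list(support_idx = support_idx, query_idx = query_idx,
                 support_y = rep(seq_len(N), each = k),
                 query_y = rep(seq_len(N), each = q),
                 classes = classes, N = N, k = k, q = q),
            class = "pcnet_episode")
}

#' Class-mean prototypes
#'
#' One prototype per episode class: the mean of that class's support
#' embeddings (permutation-invariant in the support set).
#'
#' @param embeddings Support embeddings (N*k x D).
#' @param labels Episode labels 1..N.
#' @param N Number of episode classes.
#' @return An N x D prototype matrix.
#' @export
compute_prototypes <- function(embeddings, labels, N = max(labels)) {
  proto <- matrix(0, N, ncol(embeddings))
  for (c in seq_len(N))
    proto[c, ] <- colMeans(embeddings[labels == c, , drop = FALSE])
  proto
}

#' Episode logits: negative squared distances to prototypes
#'
#' Scores are `-||z_q - p_c||^2`; class probabilities are their softmax
#' (translation-invariant in embedding space).
#'
#' @param query Query embeddings (n_q x D).
#' @param prototypes Prototype matrix (N x D).
#' @return n_q x N logit matrix.
#' @export
episode_logits <- function(query, prototypes) {
  -(outer(rowSums(query^2), rowSums(prototypes^2), `+`) -
      2 * query %*% t(prototypes))
}

# Analytic gradient of the episode cross-entropy with respect to both query
# and support embeddings (support enters through the prototypes).
proto_loss_grad <- function(emb_s, emb_q, sy, qy, N, k) {
  proto <- compute_prototypes(emb_s, sy, N)
  logits <- episode_logits(emb_q, proto)
  p <- softmax_rows(logits)
  Y <- one_hot(qy, N)
  nq <- nrow(emb_q)
  A <- (p - Y) / nq                      # dL/dlogits
  # dL/dz_q = sum_c A_qc * (-2)(z_q - proto_c)
  gq <- -2 * (rowSums(A) * emb_q - A %*% proto)
  # dL/dproto_c = sum_q A_qc * 2 (z_q - proto_c); spread over the k supports
  gp <- 2 * (t(A) %*% emb_q - colSums(A) * proto)
  gs <- gp[sy, , drop = FALSE] / k
  list(loss = -mean(rowSums(Y * log(pmax(p, 1e-300)))), g_query = gq,
       g_support = gs, logits = logits)
}

# Embed a whole bank deterministically. Evaluation chunks share batch-norm
# statistics, so rows are passed through in a fixed shuffled order (class
# banks are stored class-blocked; shuffling decorrelates chunk composition
# from class identity) and unshuffled afterwards.
embed_bank <- function(spec, params, x, chunk = 128L) {
  n <- nrow(x)
  set.seed(20240601)
  perm <- sample.int(n)
  emb <- predict_outputs(spec, params, x[perm, , drop = FALSE], chunk = chunk)
  out <- matrix(0, n, ncol(emb))
  out[perm, ] <- emb
  out
}

#' Evaluate few-shot accuracy over seeded episodes
#'
#' Embeds the whole bank once (deterministic evaluation mode, fixed chunking),
#' then averages query accuracy over `episodes` seeded N-way k-shot episodes.
#'
#' @param spec,params Encoder network and parameters.
#' @param bank Class bank.
#' @param N,k,q Episode shape.
#' @param episodes Number of evaluation episodes (default 1000).
#' @param seed Integer seed.
#' @return `list(mean, se, ci95, per_episode)`: mean accuracy in percent, its
#'   standard error, and a 95% interval half-width.
#' @export
evaluate_fewshot <- function(spec, params, bank, N, k, q = 15L,
                             episodes = 1000L, seed = 1L) {
  emb <- embed_bank(spec, params, bank$x)
  acc <- numeric(episodes)
  for (ep in seq_len(episodes)) {
    e <- sample_episode(bank, N, k, q, seed = derive_seed(seed, ep))
    proto <- compute_prototypes(emb[e$support_idx, , drop = FALSE], e$support_y, N)
    logits <- episode_logits(emb[e$query_idx, , drop = FALSE], proto)
    acc[ep] <- accuracy_pct(max.col(logits, ties.method = "first"), e$query_y)
  }
  se <- stats::sd(acc) / sqrt(episodes)
  list(mean = mean(acc), se = se, ci95 = 1.96 * se, per_episode = acc)
}

#' Chance-level calibration of the episodic evaluator
#'
#' Runs [evaluate_fewshot()] on independent pure-noise class banks — inputs
#' i.i.d. Gaussian, labels uninformative by exchangeability — so the true
#' episode accuracy is exactly `100/N` percent. Averaging over banks as well
#' as episodes makes the standard error honest (a single fixed bank carries a
#' bank-level bias that does not shrink with more episodes). A calibrated
#' evaluator must land within sampling error of chance.
#'
#' @param spec,params Encoder and parameters.
#' @param N,k,q Episode shape.
#' @param n_banks Number of independent noise banks.
#' @param episodes_per_bank Episodes sampled per bank.
#' @param bank_classes,bank_items Noise-bank shape (classes x items).
#' @param image_shape Input image shape.
#' @param seed Integer seed.
#' @return `list(mean, se, chance, n_episodes)`.
#' @export
fewshot_null_calibration <- function(spec, params, N, k = 1L, q = 15L,
                                     n_banks = 20L, episodes_per_bank = 50L,
                                     bank_classes = 40L, bank_items = 20L,
                                     image_shape = c(16L, 16L, 1L), seed = 1L) {
  d <- prod(image_shape)
  accs <- numeric(0)
  for (b in seq_len(n_banks)) {
    set.seed(derive_seed(seed, 70000 + b))
    nb <- list(x = matrix(stats::rnorm(bank_classes * bank_items * d),
                          bank_classes * bank_items, d),
               y = rep(seq_len(bank_classes), each = bank_items),
               n_classes = bank_classes, image_shape = image_shape)
    r <- evaluate_fewshot(spec, params, nb, N, k, q,
                          episodes = episodes_per_bank,
                          seed = derive_seed(seed, b))
    accs <- c(accs, r$per_episode)
  }
  list(mean = mean(accs), se = stats::sd(accs) / sqrt(length(accs)),
       chance = 100 / N, n_episodes = length(accs))
}

#' Default few-shot training configuration
#'
#' Learning rate 1e-3 reduced by 1/10 every 20 epochs, weight decay 2e-4;
#' predictive coding uses the same rates with 20 inference iterations under
#' the fixed prediction assumption. Training episodes default to the
#' evaluation shape.
#'
#' @param algorithm `"bp"` or `"pc"`.
#' @param ... Overrides.
#' @export
fewshot_config <- function(algorithm = "bp", ...) {
  cfg <- list(lr = 1e-3, step_every = 20L, step_factor = 0.1,
              weight_decay = 2e-4, epochs = 10L, episodes_per_epoch = 20L,
              train_N = 5L, train_k = 5L, train_q = 15L,
              eta_v = 0.1, pc_iters = 20L, fixed_predictions = TRUE)
  utils::modifyList(cfg, list(...))
}

#' Episodic training of a prototypical-network encoder
#'
#' Minimizes the query cross-entropy of each training episode. Under
#' backpropagation the embedding gradient is chained through the encoder;
#' under predictive coding it is injected as the output error node of the
#' embedding layer and all other layers learn through the local rule after
#' the inference loop.
#'
#' @param spec Encoder (e.g. [make_protonet4()]).
#' @param bank Training class bank.
#' @param algorithm `"bp"` or `"pc"`.
#' @param config From [fewshot_config()].
#' @param seed Integer seed.
#' @return `list(params, history)` with per-epoch mean episode loss.
#' @export
train_fewshot <- function(spec, bank, algorithm = c("bp", "pc"),
                          config = fewshot_config(algorithm), seed = 1L) {
  algorithm <- match.arg(algorithm)
  params <- init_params(spec, seed)
  lr <- config$lr
  hist <- data.frame()
  L <- spec$n_layers
  for (ep in seq_len(config$epochs)) {
    losses <- numeric(config$episodes_per_epoch)
    for (it in seq_len(config$episodes_per_epoch)) {
      e <- sample_episode(bank, config$train_N, config$train_k, config$train_q,
                          seed = derive_seed(seed, ep * 10000 + it))
      idx <- c(e$support_idx, e$query_idx)
      state <- forward_pass(spec, params, bank$x[idx, , drop = FALSE],
                            training = TRUE)
      emb <- state$vhat[[L]]
      ns <- length(e$support_idx)
      pl <- proto_loss_grad(emb[seq_len(ns), , drop = FALSE],
                            emb[ns + seq_along(e$query_idx), , drop = FALSE],
                            e$support_y, e$query_y, e$N, e$k)
      losses[it] <- pl$loss
      e_L <- rbind(pl$g_support, pl$g_query)  # dL/d(embedding), e-convention
      if (algorithm == "bp") {
        delta <- e_L
        g <- vector("list", L)
        for (i in rev(seq_len(L))) {
          gi <- layer_pgrad(spec$layers[[i]], params[[i]], state$ctx[[i]], delta)
          g[[i]] <- lapply(gi, function(v) -v)
          if (i > 1) delta <- layer_jtv(spec$layers[[i]], params[[i]],
                                        state$ctx[[i]], delta)
        }
        grads <- structure(g, class = "pcnet_grads")
      } else {
        state$e[[L]] <- e_L
        state$coupling <- list(objective = "episodic", args = list())
        state$clamped <- FALSE
        state$target <- emb
        inf <- run_inference(state, spec, params, eta_v = config$eta_v,
                             max_iters = config$pc_iters,
                             fixed_predictions = config$fixed_predictions)
        grads <- weight_gradient(inf$state, spec, params)
      }
      params <- apply_update(params, grads, lr, config$weight_decay)
    }
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr, loss = mean(losses)))
    if (ep %% config$step_every == 0) lr <- lr * config$step_factor
  }
  list(params = params, history = hist)
}
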