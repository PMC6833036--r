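#' Training configuration for the three regimes
#'
#' Regime I trains from scratch (intended for the larger driving corpus),
#' regime II trains from scratch on the mental-arithmetic corpus, and
#' regime III fine-tunes a regime-I pretrained network with stages 1-7
#' frozen (only the last stage and the softmax head are updated, the head
#' having been re-initialized; see [prepare_transfer()]). Defaults: batch
#' size 64, at most 10 epochs, Adam (beta1 = 0.9, beta2 = 0.999,
#' eps = 1e-8), base learning rate 1e-3 (I, II) or 1e-4 (III), decayed by
#' a factor of 10 every 5 epochs, dropout 0.3.
#'
#' @param regime `"I"`, `"II"` or `"III"`.
#' @param batch_size mini-batch size `m`.
#' @param max_epochs epoch cap.
#' @param base_lr initial learning rate; default depends on regime.
#' @param lr_decay_factor,lr_decay_every step-decay schedule.
#' @param beta1,beta2,eps Adam moments and stabilizer.
#' @param frozen_stages integer stages whose parameters (and batch-norm
#'   running statistics) are kept bit-identical; default `1:7` for regime
#'   III, none otherwise.
#' @param seed integer seed controlling shuffling and dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(regime = c("II", "I", "III"), batch_size = 64L,
                         max_epochs = 10L, base_lr = NULL,
                         lr_decay_factor = 0.1, lr_decay_every = 5L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         frozen_stages = NULL, seed = 1L) {
  regime <- match.arg(regime)
  base_lr <- base_lr %||% if (regime == "III") 1e-4 else 1e-3
  frozen_stages <- frozen_stages %||%
    if (regime == "III") 1:7 else integer(0)
  if (length(frozen_stages) && (min(frozen_stages) < 1 || max(frozen_stages) > 8))
    abort("frozen_stages must be a subset of 1..8")
  if (batch_size < 1 || max_epochs < 1) abort("batch_size/max_epochs must be >= 1")
  structure(list(regime = regime, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), base_lr = base_lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 frozen_stages = as.integer(sort(unique(frozen_stages))),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Binary cross-entropy loss
#'
#' `L = -(1/m) * sum(y * log(h) + (1 - y) * log(1 - h))` over a mini-batch,
#' with `h` the predicted stress probability. Probabilities are clipped to
#' `[1e-12, 1 - 1e-12]` to guard `log(0)`.
#'
#' @param h predicted stress probabilities.
#' @param y true labels in `{0, 1}`.
#' @param m batch size (defaults to `length(h)`).
#' @return non-negative scalar loss.
#' @export
#' @examples
#' cross_entropy(rep(0.5, 4), c(0, 1, 0, 1))  # log(2)
cross_entropy <- function(h, y, m = length(h)) {
  if (length(h) != length(y)) abort("h and y must have equal length")
  if (!all(y %in% c(0, 1))) abort("labels must be 0/1")
  h <- pmin(pmax(h, 1e-12), 1 - 1e-12)
  -sum(y * log(h) + (1 - y) * log(1 - h)) / m
}

#' Learning rate at a given epoch
#'
#' Step decay: `base_lr * lr_decay_factor^(epoch %/% lr_decay_every)`,
#' with `epoch` counted from 0.
#'
#' @param cfg a [train_config()].
#' @param epoch 0-based epoch index.
#' @return learning rate.
#' @export
#' @examples
#' lr_at_epoch(train_config("I"), 5)  # 1e-4
lr_at_epoch <- function(cfg, epoch) {
  if (!inherits(cfg, "train_config")) abort("cfg must be a train_config")
  if (any(epoch < 0)) abort("epoch must be >= 0")
  cfg$base_lr * cfg$lr_decay_factor^(epoch %/% cfg$lr_decay_every)
}

adam_state_new <- function() list(t = 0L, m = list(), v = list())

# standard Adam (divides by sqrt(v_hat) + eps)
adam_update <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- state$m[[nm]]
    v <- state$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- cfg$beta1 * m + (1 - cfg$beta1) * g
    v <- cfg$beta2 * v + (1 - cfg$beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + cfg$eps)
  }
  list(params = params, state = state)
}

# contiguous frozen prefix 1..F (0 if stage 1 is trainable)
frozen_prefix <- function(frozen) {
  f <- 0L
  while ((f + 1L) %in% frozen) f <- f + 1L
  f
}

#' Train the network
#'
#' Runs mini-batch Adam for up to `max_epochs` epochs (one epoch = one full
#' pass over shuffled training windows) and returns the epoch snapshot with
#' the highest test-set accuracy (the training-set accuracy when no test
#' set is given; earliest epoch wins ties). Frozen stages are never
#' updated: their weights, batch-norm parameters and running statistics
#' stay bit-identical, and they run in inference mode (running statistics,
#' no dropout). When the frozen set is a prefix `1..F`, features at stage
#' `F` are precomputed once and only the remaining stages are iterated.
#'
#' @param net a `stress_net` (He-initialized for regimes I/II; prepared by
#'   [prepare_transfer()] for regime III).
#' @param ds training `windowed_dataset`.
#' @param cfg a [train_config()].
#' @param test_ds optional held-out `windowed_dataset` used for model
#'   selection and the per-epoch test accuracy.
#' @return object of class `train_fit`: list with `net` (selected
#'   snapshot), `log` (per-epoch data.frame: epoch, lr, loss, train_acc,
#'   test_acc), `best_epoch`, `cfg`.
#' @export
train <- function(net, ds, cfg, test_ds = NULL) {
  if (!inherits(net, "stress_net")) abort("net must be a stress_net")
  if (!inherits(ds, "windowed_dataset")) abort("ds must be a windowed_dataset")
  if (!inherits(cfg, "train_config")) abort("cfg must be a train_config")
  n <- length(ds$y)
  if (n == 0) abort("training dataset is empty")
  if (cfg$regime == "III" && !isTRUE(net$meta$transfer_prepared))
    abort("regime III requires a network prepared from a pretrained checkpoint (see prepare_transfer)")
  frozen <- cfg$frozen_stages
  net$meta$frozen_stages <- frozen
  F <- frozen_prefix(frozen)
  fast <- F >= 1L && setequal(frozen, seq_len(F))
  from_stage <- if (fast) F + 1L else 1L
  if (fast) {
    Xtr <- cache_features(net, ds$x, upto = F)
    Xte <- if (!is.null(test_ds)) cache_features(net, test_ds$x, upto = F)
  } else {
    Xtr <- arr3(ds$x)
    Xte <- if (!is.null(test_ds)) arr3(test_ds$x)
  }
  trainable <- setdiff(seq_len(net$cfg$n_stages), frozen)
  min_stage <- if (length(trainable)) min(trainable) else net$cfg$n_stages + 1L
  state <- adam_state_new()
  log <- data.frame()
  best <- list(acc = -Inf, epoch = NA_integer_, net = NULL)
  set.seed(derive_seed(cfg$seed, "train", cfg$regime))
  for (epoch in 0:(cfg$max_epochs - 1L)) {
    lr <- lr_at_epoch(cfg, epoch)
    idx <- sample.int(n)
    losses <- accs <- wts <- numeric(0)
    for (lo in seq(1L, n, by = cfg$batch_size)) {
      bidx <- idx[lo:min(lo + cfg$batch_size - 1L, n)]
      Xb <- Xtr[, , bidx, drop = FALSE]
      yb <- ds$y[bidx]
      m <- length(bidx)
      fw <- net_forward(net, Xb, training = TRUE, from_stage = from_stage,
                        keep_cache = TRUE,
                        eval_stages = if (fast) integer(0) else frozen)
      net$running <- fw$running
      h <- fw$probs[, 2L]
      losses <- c(losses, cross_entropy(h, yb, m))
      accs <- c(accs, mean((h > 0.5) == (yb == 1L)))
      wts <- c(wts, m)
      Y1 <- cbind(1 - yb, yb)
      dlogits <- (fw$probs - Y1) / m
      grads <- net_backward(net, fw, dlogits,
                            min_stage = max(min_stage, from_stage),
                            skip_w = frozen)
      upd <- adam_update(net$params, grads, state, lr, cfg)
      net$params <- upd$params
      state <- upd$state
    }
    train_acc <- sum(accs * wts) / sum(wts)
    test_acc <- NA_real_
    if (!is.null(test_ds)) {
      pte <- infer_probs(net, Xte, from_stage = from_stage)
      test_acc <- mean((pte[, 2L] > 0.5) == (test_ds$y == 1L))
    }
    sel <- if (!is.null(test_ds)) test_acc else train_acc
    if (sel > best$acc) {
      best$acc <- sel
      best$epoch <- epoch
      best$net <- net
    }
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 loss = sum(losses * wts) / sum(wts),
                                 train_acc = train_acc,
                                 test_acc = test_acc))
  }
  out_net <- best$net
  out_net$meta$regime <- cfg$regime
  structure(list(net = out_net, log = log, best_epoch = best$epoch,
                 cfg = cfg),
            class = "train_fit")
}

# eval-mode features sigma(upto) for a whole dataset, batched
cache_features <- function(net, X, upto, batch_size = 256L) {
  A <- arr3(X)
  n <- dim(A)[3L]
  out <- NULL
  for (lo in seq(1L, n, by = batch_size)) {
    hi <- min(lo + batch_size - 1L, n)
    fw <- net_forward(net, A[, , lo:hi, drop = FALSE], training = FALSE,
                      upto_stage = upto, with_head = FALSE)
    if (is.null(out))
      out <- array(0, dim = c(dim(fw$feat)[1:2], n))
    out[, , lo:hi] <- fw$feat
  }
  out
}

#' Prepare a pretrained network for transfer learning
#'
#' Copies all stage parameters and batch-norm running statistics from a
#' pretrained checkpoint, re-initializes the softmax head with the He
#' scheme, and marks stages 1-7 frozen so that subsequent regime-III
#' training updates only the last stage and the head.
#'
#' @param pretrained a `stress_net` or a checkpoint path
#'   (see [save_checkpoint()]).
#' @param seed seed for the head re-initialization.
#' @param cfg optional [model_config()] that the checkpoint must match
#'   (window length, channel mode, stage count); mismatch is an error.
#' @return a `stress_net` ready for regime-III [train()].
#' @export
prepare_transfer <- function(pretrained, seed = 1L, cfg = NULL) {
  net <- if (is.character(pretrained)) load_checkpoint(pretrained)
         else pretrained
  if (!inherits(net, "stress_net")) abort("pretrained must be a stress_net or path")
  if (!is.null(cfg)) {
    for (f in c("window_s", "channel_mode", "n_stages"))
      if (!identical(net$cfg[[f]], cfg[[f]]))
        abort("pretrained checkpoint incompatible with target config: %s is %s, expected %s",
              f, format(net$cfg[[f]]), format(cfg[[f]]),
              class = "stressecg_config_error")
  }
  net <- reinit_head(net, seed)
  net$meta$transfer_prepared <- TRUE
  net$meta$frozen_stages <- seq_len(net$cfg$n_stages - 1L)
  net$meta$pretrained_regime <- net$meta$regime
  net
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the configuration, all parameter tensors keyed by
#' (stage, layer, role), batch-norm running statistics, and the
#' training-regime provenance.
#'
#' @param net a `stress_net`.
#' @param path file path.
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: a
#'   `stress_net`.
#' @export
save_checkpoint <- function(net, path) {
  if (!inherits(net, "stress_net")) abort("net must be a stress_net")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(unclass(net), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort("checkpoint '%s' not found", path)
  structure(readRDS(path), class = "stress_net")
}
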