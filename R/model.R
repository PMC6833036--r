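#' Configuration of the dual-branch convolutional network
#'
#' The network stacks `n_stages` stages. Stage `N` applies a width-16
#' convolution (stride 1, same padding), feeds its output to two parallel
#' subsampling branches -- a width-16 strided convolution (stride 2) and a
#' width-16 max-pooling (stride 2) -- concatenates the branch outputs along
#' channels, then batch normalization, rectified-linear activation and
#' dropout. Width halves at every stage, so the stage-`N` feature map has
#' shape `[m, w / 2^N, c(N)]` with `w = 256 * window_s` and channel
#' schedule `c(N) = 8 * 2^k`, `k = floor((N - 1) / 2)` (8, 8, 16, 16, 32,
#' 32, 64, 64). A flatten + linear + softmax head yields two class
#' probabilities.
#'
#' `channel_mode` resolves a bookkeeping ambiguity between the stated
#' channel schedule (which counts the *concatenated* stage output, so each
#' branch carries `c(N) / 2` channels -- the default, `"equations"`) and a
#' literal reading of the per-layer filter table (each conv has `c(N)`
#' filters, so stage outputs double to 16..128 -- `"table3"`).
#'
#' @param window_s window length in seconds (10, 30 or 60).
#' @param fs sampling rate, Hz; the architecture assumes 256.
#' @param n_stages number of stages (default 8).
#' @param channel_mode `"equations"` (default) or `"table3"`.
#' @param dropout dropout rate (default 0.3).
#' @param bn_momentum batch-norm running-statistics momentum (default 0.99).
#' @param bn_eps batch-norm variance epsilon (default 1e-5).
#' @return an object of class `model_config`.
#' @export
model_config <- function(window_s, fs = 256, n_stages = 8L,
                         channel_mode = c("equations", "table3"),
                         dropout = 0.3, bn_momentum = 0.99, bn_eps = 1e-5) {
  channel_mode <- match.arg(channel_mode)
  stopifnot_scalar_num(window_s, "window_s")
  stopifnot_scalar_num(fs, "fs")
  w <- as.integer(round(fs * window_s))
  if (w %% 2L^n_stages != 0L)
    abort("input width %d is not divisible by 2^%d", w, n_stages,
          class = "stressecg_config_error")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  structure(list(window_s = window_s, fs = fs, w = w,
                 n_stages = as.integer(n_stages),
                 channel_mode = channel_mode, dropout = dropout,
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 n_classes = 2L),
            class = "model_config")
}

# concatenated output channels of stage N
stage_channels <- function(cfg, N) {
  base <- as.integer(8 * 2^((N - 1L) %/% 2L))
  if (cfg$channel_mode == "table3") 2L * base else base
}

# channels per subsampling branch (= first conv's filter count)
branch_channels <- function(cfg, N) stage_channels(cfg, N) %/% 2L

#' Closed-form output shape of a stage
#'
#' Returns the feature-map shape `(width, channels)` the architecture's
#' dimension equations prescribe for stage `N`; probe-batch tests verify
#' that a built network produces exactly these shapes.
#'
#' @param cfg a [model_config()].
#' @param N stage index in `1..n_stages`.
#' @return named integer vector `c(width, channels)`.
#' @export
#' @examples
#' stage_output_shape(model_config(10), 8)  # width 10, 64 channels
stage_output_shape <- function(cfg, N) {
  if (!inherits(cfg, "model_config")) abort("cfg must be a model_config")
  if (length(N) != 1L || N < 1L || N > cfg$n_stages)
    abort("N must lie in 1..%d, got %s", cfg$n_stages, format(N))
  c(width = as.integer(cfg$w %/% 2^as.integer(N)),
    channels = stage_channels(cfg, as.integer(N)))
}

stage_in_channels <- function(cfg, N) {
  if (N == 1L) 1L else stage_channels(cfg, N - 1L)
}

#' Build the stress-detection network
#'
#' Allocates all parameters (convolution weights/biases, batch-norm
#' gamma/beta and running statistics, softmax head) and applies He
#' initialization.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for the initialization.
#' @return an object of class `stress_net`.
#' @export
build_model <- function(cfg, seed = 1L) {
  if (!inherits(cfg, "model_config")) abort("cfg must be a model_config")
  params <- list()
  running <- list()
  k <- FILTER_WIDTH
  for (N in seq_len(cfg$n_stages)) {
    cin <- stage_in_channels(cfg, N)
    br <- branch_channels(cfg, N)
    cout <- stage_channels(cfg, N)
    params[[sprintf("s%d.conv1.W", N)]] <- matrix(0, k * cin, br)
    params[[sprintf("s%d.conv1.b", N)]] <- numeric(br)
    params[[sprintf("s%d.conv2.W", N)]] <- matrix(0, k * br, br)
    params[[sprintf("s%d.conv2.b", N)]] <- numeric(br)
    params[[sprintf("s%d.bn.gamma", N)]] <- rep(1, cout)
    params[[sprintf("s%d.bn.beta", N)]] <- numeric(cout)
    running[[sprintf("s%d", N)]] <- list(mean = numeric(cout),
                                         var = rep(1, cout))
  }
  d_head <- (cfg$w %/% 2L^cfg$n_stages) * stage_channels(cfg, cfg$n_stages)
  params[["head.W"]] <- matrix(0, d_head, cfg$n_classes)
  params[["head.b"]] <- numeric(cfg$n_classes)
  net <- structure(list(cfg = cfg, params = params, running = running,
                        meta = list(regime = NULL,
                                    frozen_stages = integer(0))),
                   class = "stress_net")
  he_initialize(net, seed)
}

#' He (re-)initialization of all weights
#'
#' Draws every convolutional and linear weight from `N(0, 2 / n_in)` where
#' `n_in` is the layer fan-in (`filter_width * in_channels` for
#' convolutions, the flattened feature length for the head); biases are
#' zero, batch-norm gamma = 1, beta = 0, running statistics reset.
#'
#' @param net a `stress_net`.
#' @param seed integer seed.
#' @return the re-initialized `stress_net`.
#' @export
he_initialize <- function(net, seed = 1L) {
  if (!inherits(net, "stress_net")) abort("net must be a stress_net")
  with_seed(seed, {
    for (nm in names(net$params)) {
      p <- net$params[[nm]]
      if (grepl("\\.W$", nm)) {
        n_in <- nrow(p)
        net$params[[nm]] <- matrix(rnorm(length(p), 0, sqrt(2 / n_in)),
                                   nrow(p), ncol(p))
      } else if (grepl("\\.b$", nm)) {
        net$params[[nm]] <- numeric(length(p))
      } else if (grepl("\\.gamma$", nm)) {
        net$params[[nm]] <- rep(1, length(p))
      } else if (grepl("\\.beta$", nm)) {
        net$params[[nm]] <- numeric(length(p))
      }
    }
  })
  for (nm in names(net$running))
    net$running[[nm]] <- list(mean = numeric(length(net$running[[nm]]$mean)),
                              var = rep(1, length(net$running[[nm]]$var)))
  net
}

# Re-initialize only the softmax head (transfer learning), He scheme.
reinit_head <- function(net, seed) {
  with_seed(seed, {
    W <- net$params[["head.W"]]
    net$params[["head.W"]] <- matrix(rnorm(length(W), 0, sqrt(2 / nrow(W))),
                                     nrow(W), ncol(W))
    net$params[["head.b"]] <- numeric(length(net$params[["head.b"]]))
  })
  net
}

# Forward pass. X: [w, c, m] array (or [w, m] matrix, single channel) holding
# sigma(from_stage - 1). `eval_stages` run in inference mode (running BN
# stats, no dropout) even when training = TRUE. Returns logits/probs and,
# if keep_cache, per-stage caches for backprop. Mutates nothing; updated BN
# running stats are returned in $running.
net_forward <- function(net, X, training = FALSE, from_stage = 1L,
                        upto_stage = NULL, with_head = TRUE,
                        keep_cache = FALSE, eval_stages = integer(0)) {
  cfg <- net$cfg
  upto_stage <- upto_stage %||% cfg$n_stages
  A <- arr3(X)
  expect_w <- cfg$w %/% 2L^(from_stage - 1L)
  if (dim(A)[1L] != expect_w)
    abort("expected input width %d at stage %d, got %d",
          expect_w, from_stage, dim(A)[1L], class = "stressecg_shape_error")
  caches <- list()
  running <- net$running
  k <- FILTER_WIDTH
  for (N in seq(from_stage, length.out = upto_stage - from_stage + 1L)) {
    p <- net$params
    trn <- training && !(N %in% eval_stages)
    A1 <- cpp_conv1d_fwd(A, p[[sprintf("s%d.conv1.W", N)]],
                         p[[sprintf("s%d.conv1.b", N)]], k, 1L)
    C <- cpp_conv1d_fwd(A1, p[[sprintf("s%d.conv2.W", N)]],
                        p[[sprintf("s%d.conv2.b", N)]], k, 2L)
    pool <- cpp_maxpool_fwd(A1, k, 2L)
    br <- dim(C)[2L]
    S <- array(0, dim = c(dim(C)[1L], 2L * br, dim(C)[3L]))
    S[, seq_len(br), ] <- C
    S[, br + seq_len(br), ] <- pool$Y
    bn <- bn_forward(S, p[[sprintf("s%d.bn.gamma", N)]],
                     p[[sprintf("s%d.bn.beta", N)]],
                     running[[sprintf("s%d", N)]],
                     cfg$bn_momentum, cfg$bn_eps, training = trn)
    if (trn) running[[sprintf("s%d", N)]] <- bn$running
    R <- bn$Y
    relu_mask <- R > 0
    R[!relu_mask] <- 0
    if (trn && cfg$dropout > 0) {
      dp <- dropout_forward(R, cfg$dropout)
      out <- dp$Y
      dmask <- dp$mask
    } else {
      out <- R
      dmask <- NULL
    }
    if (keep_cache)
      caches[[N]] <- list(X = A, A1 = A1, pool_idx = pool$idx,
                          br = br, bn_cache = bn$cache,
                          relu_mask = relu_mask, dmask = dmask,
                          trained = trn)
    A <- out
  }
  res <- list(feat = A, caches = caches, running = running)
  if (with_head && upto_stage == cfg$n_stages) {
    d <- dim(A)
    Xf <- A
    dim(Xf) <- c(d[1L] * d[2L], d[3L])
    Z <- crossprod(Xf, net$params[["head.W"]])        # [m, 2]
    Z <- sweep(Z, 2L, net$params[["head.b"]], "+")
    res$logits <- Z
    res$probs <- softmax_rows(Z)
    res$flat <- Xf
    res$feat_dim <- d
  }
  res
}

# Backward pass from dlogits [m, 2]; computes gradients for stages
# >= min_stage (weight gradients skipped for stages in `skip_w`).
net_backward <- function(net, fw, dlogits, min_stage = 1L,
                         skip_w = integer(0)) {
  cfg <- net$cfg
  grads <- list()
  grads[["head.W"]] <- fw$flat %*% dlogits
  grads[["head.b"]] <- colSums(dlogits)
  dX <- net$params[["head.W"]] %*% t(dlogits)          # [d, m]
  dA <- array(dX, dim = fw$feat_dim)
  k <- FILTER_WIDTH
  for (N in seq(cfg$n_stages, min_stage)) {
    cc <- fw$caches[[N]]
    if (is.null(cc)) abort("no cache for stage %d", N)
    if (!is.null(cc$dmask)) dA <- dA * cc$dmask
    dA[!cc$relu_mask] <- 0
    bb <- bn_backward(dA, net$params[[sprintf("s%d.bn.gamma", N)]],
                      cc$bn_cache)
    need_w <- !(N %in% skip_w)
    if (need_w) {
      grads[[sprintf("s%d.bn.gamma", N)]] <- bb$dgamma
      grads[[sprintf("s%d.bn.beta", N)]] <- bb$dbeta
    }
    br <- cc$br
    dC <- bb$dX[, seq_len(br), , drop = FALSE]
    dP <- bb$dX[, br + seq_len(br), , drop = FALSE]
    g2 <- cpp_conv1d_bwd(cc$A1, net$params[[sprintf("s%d.conv2.W", N)]],
                         dC, k, 2L, TRUE, need_w)
    dA1 <- g2$dX + cpp_maxpool_bwd(cc$pool_idx, dP, dim(cc$A1)[1L])
    need_dx <- N > min_stage
    g1 <- cpp_conv1d_bwd(cc$X, net$params[[sprintf("s%d.conv1.W", N)]],
                         dA1, k, 1L, need_dx, need_w)
    if (need_w) {
      grads[[sprintf("s%d.conv2.W", N)]] <- g2$dW
      grads[[sprintf("s%d.conv2.b", N)]] <- g2$db
      grads[[sprintf("s%d.conv1.W", N)]] <- g1$dW
      grads[[sprintf("s%d.conv1.b", N)]] <- g1$db
    }
    if (need_dx) dA <- g1$dX
  }
  grads
}

# batched inference forward; returns probs matrix [n, 2] (rest, stress)
infer_probs <- function(net, X, from_stage = 1L, batch_size = 256L) {
  A <- arr3(X)
  n <- dim(A)[3L]
  probs <- matrix(NA_real_, n, 2L,
                  dimnames = list(NULL, c("rest", "stress")))
  for (lo in seq(1L, n, by = batch_size)) {
    hi <- min(lo + batch_size - 1L, n)
    fw <- net_forward(net, A[, , lo:hi, drop = FALSE], training = FALSE,
                      from_stage = from_stage)
    probs[lo:hi, ] <- fw$probs
  }
  probs
}

#' Predict class probabilities for ECG windows
#'
#' Runs the network in inference mode (dropout disabled, batch-norm using
#' stored running statistics). Probabilities in each row sum to 1; the
#' predicted label is the argmax (stress when `P(stress) > 0.5`).
#'
#' @param object a `stress_net`.
#' @param newdata a `windowed_dataset`, a `[w, n]` matrix, or a
#'   `[w, 1, n]` array.
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return list with `prob` (`n x 2` matrix, columns rest/stress) and
#'   `label` (integer vector, 0 = rest, 1 = stress).
#' @export
predict.stress_net <- function(object, newdata, batch_size = 256L, ...) {
  X <- if (inherits(newdata, "windowed_dataset")) newdata$x else newdata
  A <- arr3(X)
  if (dim(A)[1L] != object$cfg$w)
    abort("expected input width %d, got %d", object$cfg$w, dim(A)[1L],
          class = "stressecg_shape_error")
  probs <- infer_probs(object, A, batch_size = batch_size)
  list(prob = probs, label = as.integer(probs[, "stress"] > 0.5))
}

#' @export
print.stress_net <- function(x, ...) {
  npar <- sum(vapply(x$params, length, 0L))
  cat(sprintf(paste0("<stress_net> %d stages, window %g s (w = %d), ",
                     "channel_mode = %s, %d parameters\n"),
              x$cfg$n_stages, x$cfg$window_s, x$cfg$w, x$cfg$channel_mode,
              npar))
  if (length(x$meta$frozen_stages))
    cat("  frozen stages:", paste(x$meta$frozen_stages, collapse = ", "), "\n")
  invisible(x)
}

#' Parameter and running-statistic checksums
#'
#' MD5 digests of every parameter tensor and batch-norm running statistic,
#' keyed by name -- used to verify the freezing contract of transfer
#' learning bit-exactly.
#'
#' @param net a `stress_net`.
#' @param stages integer vector of stages to include (default all, plus
#'   the head when `head = TRUE`).
#' @param head include head parameters.
#' @return named character vector of digests.
#' @export
param_checksums <- function(net, stages = seq_len(net$cfg$n_stages),
                            head = FALSE) {
  out <- character(0)
  for (nm in names(net$params)) {
    sN <- regmatches(nm, regexpr("^s[0-9]+", nm))
    if (length(sN) == 1 && as.integer(sub("s", "", sN)) %in% stages)
      out[nm] <- digest::digest(net$params[[nm]])
    if (grepl("^head\\.", nm) && head) out[nm] <- digest::digest(net$params[[nm]])
  }
  for (N in stages) {
    key <- sprintf("s%d", N)
    out[paste0(key, ".bn.running")] <- digest::digest(net$running[[key]])
  }
  out
}
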