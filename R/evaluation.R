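#' Subject-wise fold plan for k-fold cross-validation
#'
#' Randomly assigns whole subjects to `k` folds (sizes as equal as
#' possible, differing by at most one), so that no subject's windows can
#' appear in both the training and the test split of any iteration. If
#' fewer than `k` subjects are available, `k` is reduced with a warning.
#'
#' @param subject_ids character vector (duplicates allowed; unique IDs are
#'   assigned).
#' @param k number of folds (default 10).
#' @param seed integer seed; identical inputs yield identical plans.
#' @return object of class `fold_plan`: list with `k`, `folds` (list of
#'   subject-ID character vectors) and `seed`.
#' @export
make_folds <- function(subject_ids, k = 10L, seed = 1L) {
  ids <- unique(as.character(subject_ids))
  if (k < 2) abort("k must be >= 2")
  if (length(ids) < k) {
    warning(sprintf("only %d subjects; reducing k from %d to %d",
                    length(ids), k, length(ids)))
    k <- length(ids)
  }
  if (length(ids) < 2) abort("need at least 2 subjects")
  perm <- with_seed(seed, sample(ids))
  folds <- split(perm, rep_len(seq_len(k), length(perm)))
  names(folds) <- NULL
  structure(list(k = as.integer(k), folds = folds, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k = %d, %d subjects, sizes: %s\n", x$k,
              length(unlist(x$folds)),
              paste(lengths(x$folds), collapse = "/")))
  invisible(x)
}

#' Confusion-matrix metrics and ROC AUC
#'
#' Predictions use the argmax rule (stress when `P(stress) > 0.5`).
#' Stress is the positive class: sensitivity (recall) is the true-positive
#' rate on stress windows, specificity the true-negative rate on rest
#' windows, and F1 the harmonic mean of precision and sensitivity. The AUC
#' is the trapezoidal area under the ROC swept over all distinct score
#' thresholds; it is `NA` (with a warning) when only one class is present.
#'
#' @param prob stress probabilities (vector) or an `n x 2` (rest, stress)
#'   probability matrix.
#' @param labels true labels in `{0, 1}`.
#' @return object of class `stress_metrics`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1`, `auc_roc`, and
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
compute_metrics <- function(prob, labels) {
  p <- if (is.matrix(prob)) prob[, ncol(prob)] else prob
  if (length(p) != length(labels)) abort("prob and labels length mismatch")
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1")
  pred <- as.integer(p > 0.5)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  auc <- if (length(unique(labels)) < 2) {
    warning("AUC undefined: labels contain a single class")
    NA_real_
  } else auc_roc(p, labels)
  structure(list(accuracy = (tp + tn) / length(labels),
                 sensitivity = sens, specificity = spec, precision = prec,
                 f1 = f1, auc_roc = auc,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "stress_metrics")
}

#' @export
print.stress_metrics <- function(x, ...) {
  cat(sprintf(paste0("<stress_metrics> acc %.3f | auc %.3f | f1 %.3f | ",
                     "sens %.3f | spec %.3f  (TP %d FP %d TN %d FN %d)\n"),
              x$accuracy, x$auc_roc, x$f1, x$sensitivity, x$specificity,
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' ROC curve over all distinct thresholds
#'
#' One point per distinct score value (prediction positive when
#' `score >= threshold`), preceded by the (0, 0) origin.
#'
#' @param scores classifier scores (higher = more stress-like).
#' @param labels true labels in `{0, 1}`; both classes required.
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1")
  P <- sum(labels == 1)
  Nn <- sum(labels == 0)
  if (P == 0 || Nn == 0) abort("ROC requires both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- which(!duplicated(s, fromLast = TRUE))
  rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
        data.frame(threshold = s[last], fpr = fp[last] / Nn,
                   tpr = tp[last] / P))
}

#' @rdname roc_curve
#' @return `auc_roc`: trapezoidal area under the ROC curve.
#' @export
auc_roc <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (head_(rc$tpr) + tail_(rc$tpr)) / 2)
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1L]

#' Precision-recall curve over all distinct thresholds
#'
#' @param scores classifier scores.
#' @param labels true labels in `{0, 1}`; at least one positive required.
#' @return data.frame with `threshold`, `recall`, `precision`; recall is
#'   non-increasing as the threshold rises.
#' @export
pr_curve <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1")
  P <- sum(labels == 1)
  if (P == 0) abort("PR curve requires at least one positive label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y == 1)
  npred <- seq_along(s)
  last <- which(!duplicated(s, fromLast = TRUE))
  data.frame(threshold = s[last], recall = tp[last] / P,
             precision = tp[last] / npred[last])
}

#' Compare per-fold accuracies across training regimes
#'
#' One-way ANOVA over regime groups followed by Tukey's honest significant
#' difference test, with significance flags at the 0.05 and 0.001 levels.
#'
#' @param acc_by_regime named list of per-fold accuracy vectors (>= 2
#'   groups of >= 2 folds each).
#' @return list with `anova_f`, `anova_p`, `tukey` (data.frame: pair,
#'   diff, lwr, upr, p_adj, sig_05, sig_001) and `degenerate` flag (TRUE
#'   when the within-group variance is ~0, making p-values unreliable).
#' @export
compare_regimes <- function(acc_by_regime) {
  if (!is.list(acc_by_regime) || length(acc_by_regime) < 2)
    abort("need >= 2 regime groups")
  if (any(lengths(acc_by_regime) < 2))
    abort("each regime needs >= 2 folds")
  df <- data.frame(
    acc = unlist(acc_by_regime, use.names = FALSE),
    regime = factor(rep(names(acc_by_regime), lengths(acc_by_regime))))
  fit <- aov(acc ~ regime, data = df)
  s <- summary(fit)[[1]]
  rss <- s["Residuals", "Sum Sq"]
  degenerate <- rss < 1e-12
  if (degenerate) warning("within-group variance is ~0; p-values unreliable")
  tk <- TukeyHSD(fit)$regime
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      sig_05 = tk[, "p adj"] < 0.05,
                      sig_001 = tk[, "p adj"] < 0.001,
                      row.names = NULL)
  list(anova_f = s["regime", "F value"], anova_p = s["regime", "Pr(>F)"],
       tukey = tukey, degenerate = degenerate)
}

#' Per-stage features and 2-D embedding
#'
#' `extract_stage_features()` runs the network in inference mode up to
#' stage `N` and flattens the feature map, giving one
#' `(w / 2^N) * c(N)`-dimensional vector per window. `embed_2d()` projects
#' feature vectors to 2-D with t-SNE (seeded) for visual inspection of
#' class separation across stages.
#'
#' @param net a `stress_net`.
#' @param newdata a `windowed_dataset`, matrix or array of windows.
#' @param N stage index in `1..n_stages`.
#' @return `extract_stage_features`: `n x d` feature matrix.
#' @export
extract_stage_features <- function(net, newdata, N) {
  if (!inherits(net, "stress_net")) abort("net must be a stress_net")
  if (length(N) != 1 || N < 1 || N > net$cfg$n_stages)
    abort("N must lie in 1..%d", net$cfg$n_stages)
  X <- if (inherits(newdata, "windowed_dataset")) newdata$x else newdata
  feats <- cache_features(net, X, upto = as.integer(N))
  d <- dim(feats)
  t(matrix(feats, d[1L] * d[2L], d[3L]))
}

#' @rdname extract_stage_features
#' @param features `n x d` numeric matrix.
#' @param seed integer seed for the embedding.
#' @param perplexity t-SNE perplexity; default adapts to `n`.
#' @return `embed_2d`: `n x 2` coordinate matrix.
#' @export
embed_2d <- function(features, seed = 1L, perplexity = NULL) {
  n <- nrow(features)
  if (n < 4) abort("need at least 4 points to embed")
  perplexity <- perplexity %||% max(2, min(30, floor((n - 1) / 3)))
  res <- with_seed(seed,
    Rtsne::Rtsne(features, dims = 2, perplexity = perplexity,
                 check_duplicates = FALSE, pca = n > 50, verbose = FALSE))
  res$Y
}

#' Subject-wise cross-validated training and evaluation
#'
#' For each fold: fits per-stressor normalization statistics on the
#' training-fold subjects only (or on all subjects when
#' `paper_exact = TRUE`, reproducing the pooled-normalization protocol),
#' slices windows, trains a fresh network (or a transfer-prepared one for
#' regime III), and computes test-fold metrics with ROC/PR curves. Records
#' are resampled to 256 Hz first if needed.
#'
#' @param records list of [ecg_record()]s (or a `synthetic_cohort`).
#' @param window_s window length (10/30/60 s).
#' @param cfg a [train_config()].
#' @param k number of folds.
#' @param seed base seed (folds, per-fold initialization and training
#'   seeds are derived from it).
#' @param paper_exact pool normalization statistics over all subjects.
#' @param pretrained `stress_net` or checkpoint path (required for regime
#'   III).
#' @param channel_mode passed to [model_config()].
#' @return object of class `eval_report`: `per_fold` metrics data.frame,
#'   `mean`/`sd` aggregates, per-fold and pooled ROC/PR curves, the fold
#'   plan and identifiers.
#' @export
evaluate_cv <- function(records, window_s, cfg, k = 10L, seed = 1L,
                        paper_exact = FALSE, pretrained = NULL,
                        channel_mode = "equations") {
  if (inherits(records, "synthetic_cohort")) records <- records$records
  if (!inherits(cfg, "train_config")) abort("cfg must be a train_config")
  if (cfg$regime == "III" && is.null(pretrained))
    abort("regime III requires a pretrained checkpoint")
  records <- lapply(records, resample_record, target_fs = 256)
  ids <- vapply(records, function(r) r$subject_id, "")
  plan <- make_folds(ids, k = k, seed = derive_seed(seed, "folds"))
  mcfg <- model_config(window_s, channel_mode = channel_mode)
  per_fold <- data.frame()
  curves <- list()
  pooled_scores <- numeric(0)
  pooled_labels <- integer(0)
  for (f in seq_len(plan$k)) {
    test_ids <- plan$folds[[f]]
    train_recs <- records[!(ids %in% test_ids)]
    stats <- fit_norm_stats(if (paper_exact) records else train_recs)
    normed <- lapply(records, apply_norm, stats = stats)
    ds <- slice_windows(normed, window_s)
    sp <- split_by_subject(ds, test_ids)
    fseed <- derive_seed(seed, "fold", f)
    net <- if (cfg$regime == "III")
      prepare_transfer(pretrained, seed = derive_seed(fseed, "head"),
                       cfg = mcfg)
    else build_model(mcfg, seed = derive_seed(fseed, "init"))
    fcfg <- cfg
    fcfg$seed <- derive_seed(fseed, "train")
    fit <- train(net, sp$train, fcfg, test_ds = sp$test)
    pr <- predict(fit$net, sp$test)
    m <- compute_metrics(pr$prob[, "stress"], sp$test$y)
    per_fold <- rbind(per_fold, data.frame(
      fold = f, n_test = length(sp$test$y),
      accuracy = m$accuracy, auc_roc = m$auc_roc, f1 = m$f1,
      sensitivity = m$sensitivity, specificity = m$specificity))
    curves[[f]] <- list(
      roc = tryCatch(roc_curve(pr$prob[, "stress"], sp$test$y),
                     error = function(e) NULL),
      pr = tryCatch(pr_curve(pr$prob[, "stress"], sp$test$y),
                    error = function(e) NULL))
    pooled_scores <- c(pooled_scores, pr$prob[, "stress"])
    pooled_labels <- c(pooled_labels, sp$test$y)
  }
  metric_cols <- c("accuracy", "auc_roc", "f1", "sensitivity", "specificity")
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[metric_cols], na.rm = TRUE),
    sd = vapply(per_fold[metric_cols], sd, 0, na.rm = TRUE),
    curves = curves,
    pooled = list(roc = roc_curve(pooled_scores, pooled_labels),
                  pr = pr_curve(pooled_scores, pooled_labels)),
    fold_plan = plan, regime = cfg$regime, window_s = window_s),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> regime %s, %g s windows, %d folds\n",
              x$regime, x$window_s, nrow(x$per_fold)))
  cat(sprintf("  accuracy %.3f +/- %.3f | AUC %.3f +/- %.3f | F1 %.3f +/- %.3f\n",
              x$mean["accuracy"], x$sd["accuracy"], x$mean["auc_roc"],
              x$sd["auc_roc"], x$mean["f1"], x$sd["f1"]))
  invisible(x)
}
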