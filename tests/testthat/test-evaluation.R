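test_that("make_folds: disjoint cover, balanced sizes, determinism", {
  ids <- sprintf("S%02d", 1:17)
  plan <- make_folds(ids, k = 10, seed = 3)
  expect_equal(plan$k, 10L)
  all_assigned <- unlist(plan$folds)
  expect_setequal(all_assigned, ids)           # union = all subjects
  expect_equal(anyDuplicated(all_assigned), 0L) # pairwise disjoint
  expect_lte(diff(range(lengths(plan$folds))), 1)  # sizes differ by <= 1
  expect_identical(make_folds(ids, 10, seed = 3)$folds, plan$folds)
  expect_false(identical(make_folds(ids, 10, seed = 4)$folds, plan$folds))
  # leakage probe: train/test subject intersection empty for every fold
  for (f in seq_len(plan$k))
    expect_length(intersect(plan$folds[[f]],
                            unlist(plan$folds[-f])), 0)
  expect_warning(plan5 <- make_folds(sprintf("S%d", 1:5), k = 10, seed = 1),
                 "reducing k")
  expect_equal(plan5$k, 5L)
  expect_error(make_folds(ids, k = 1), class = "stressecg_error")
})

test_that("confusion metrics: hand case and degenerate flags", {
  # TP=3, FN=1, TN=2, FP=2 via scores around 0.5
  p <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.9, 0.1, 0.3)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  m <- compute_metrics(p, y)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(3, 1, 2, 2))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$precision, 0.6)
  expect_equal(m$f1, 2 * 0.6 * 0.75 / (0.6 + 0.75))
  expect_equal(m$accuracy, 5 / 8)
  # perfect classifier
  mp <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$auc_roc, 1)
  # constant scores: AUC 0.5
  expect_equal(auc_roc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  # single-class labels: AUC undefined, flagged
  expect_warning(ms <- compute_metrics(c(0.2, 0.8), c(1, 1)), "AUC undefined")
  expect_true(is.na(ms$auc_roc))
})

test_that("metric algebra matches a brute-force recount on random tables", {
  with_seed(99, {
    for (i in 1:200) {
      n <- sample(4:40, 1)
      y <- rbinom(n, 1, runif(1, 0.2, 0.8))
      p <- runif(n)
      m <- suppressWarnings(compute_metrics(p, y))  # single-class draws occur
      pred <- as.integer(p > 0.5)
      expect_equal(m$tp + m$fp + m$tn + m$fn, n)
      expect_equal(m$accuracy, mean(pred == y))
      if (any(y == 1)) expect_equal(m$sensitivity,
                                    sum(pred == 1 & y == 1) / sum(y == 1))
      if (any(y == 0)) expect_equal(m$specificity,
                                    sum(pred == 0 & y == 0) / sum(y == 0))
    }
  })
})

test_that("AUC equals the normalized Mann-Whitney U statistic", {
  with_seed(7, {
    for (i in 1:100) {
      n1 <- sample(3:30, 1)
      n0 <- sample(3:30, 1)
      # ties included via rounding
      s1 <- round(rnorm(n1, 0.5), 1)
      s0 <- round(rnorm(n0, 0), 1)
      scores <- c(s1, s0)
      labels <- c(rep(1, n1), rep(0, n0))
      u <- suppressWarnings(
        wilcox.test(s1, s0, exact = FALSE, correct = FALSE)$statistic)
      expect_equal(auc_roc(scores, labels), unname(u) / (n1 * n0),
                   tolerance = 1e-12)
    }
  })
})

test_that("PR curve matches an exhaustive threshold sweep", {
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  labels <- c(1, 0, 1, 1, 0, 0)
  pc <- pr_curve(scores, labels)
  # brute force over all distinct thresholds
  for (i in seq_len(nrow(pc))) {
    t <- pc$threshold[i]
    pred <- as.integer(scores >= t)
    expect_equal(pc$recall[i], sum(pred & labels) / sum(labels))
    expect_equal(pc$precision[i], sum(pred & labels) / sum(pred))
  }
  # recall non-increasing as threshold rises
  expect_true(all(diff(pc$recall) >= 0))  # rows ordered by falling threshold
  # perfect classifier passes through (recall 1, precision 1)
  pp <- pr_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(pp$recall == 1 & pp$precision == 1))
  # all-positive predictions: precision = prevalence
  expect_equal(pp$precision[pp$recall == 1 & pp$threshold == min(pp$threshold)],
               0.5)
  expect_error(pr_curve(c(0.1, 0.2), c(0, 0)), class = "stressecg_error")
})

test_that("ROC curve sweeps all distinct thresholds from the origin", {
  scores <- c(0.7, 0.7, 0.5, 0.2)
  labels <- c(1, 0, 1, 0)
  rc <- roc_curve(scores, labels)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(nrow(rc), 4)  # origin + 3 distinct scores
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_equal(rc$fpr[nrow(rc)], 1)
})

test_that("regime comparison: ANOVA + Tukey behave on canonical cases", {
  # identical groups: F ~ 0, no significant pairs
  g <- list(I = c(0.8, 0.9, 0.85), II = c(0.8, 0.9, 0.85),
            III = c(0.8, 0.9, 0.85))
  r <- compare_regimes(g)
  expect_lt(r$anova_f, 1e-10)
  expect_false(any(r$tukey$sig_05))
  # well-separated means with tiny jitter: all pairs significant
  with_seed(5, {
    g2 <- list(I = 0.9 + rnorm(3, 0, 1e-3), II = 0.5 + rnorm(3, 0, 1e-3),
               III = 0.7 + rnorm(3, 0, 1e-3))
  })
  r2 <- compare_regimes(g2)
  expect_true(all(r2$tukey$sig_05))
  expect_lt(r2$anova_p, 0.001)
  # two-group ANOVA p equals the equal-variance t-test p (F = t^2)
  a <- c(0.6, 0.7, 0.65, 0.72)
  b <- c(0.8, 0.78, 0.9, 0.85)
  r3 <- compare_regimes(list(II = a, III = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r3$anova_p, tt$p.value, tolerance = 1e-12)
  expect_equal(r3$anova_f, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_error(compare_regimes(list(I = c(1, 2))), class = "stressecg_error")
})

test_that("stage feature extraction dimensions and embedding", {
  net <- build_model(model_config(10), seed = 3)
  X <- with_seed(6, matrix(rnorm(2560 * 12), 2560, 12))
  f8 <- extract_stage_features(net, X, 8)
  expect_equal(dim(f8), c(12, 640))      # 10 x 64
  f1 <- extract_stage_features(net, X, 1)
  expect_equal(dim(f1), c(12, 10240))    # 1280 x 8
  # identical windows give identical features
  X2 <- X; X2[, 2] <- X2[, 1]
  f <- extract_stage_features(net, X2, 8)
  expect_identical(f[1, ], f[2, ])
  expect_error(extract_stage_features(net, X, 9), class = "stressecg_error")
  emb <- embed_2d(f8, seed = 4)
  expect_equal(dim(emb), c(12, 2))
  expect_identical(emb, embed_2d(f8, seed = 4))
})

test_that("baselines: chance on permuted labels, LR solves a separable toy", {
  ds <- make_toy_dataset(n = 120, w = 512, offset = 2, seed = 31,
                         n_subjects = 6)
  ds$window_s <- 2  # bypass slice-time restriction; features are generic here
  folds <- make_folds(unique(ds$subject_id), k = 3, seed = 2)
  # separable: logistic regression >= 0.95
  rep1 <- run_baselines(ds, folds, classifiers = "logistic_regression",
                        seed = 5)
  expect_gte(rep1$summary$mean, 0.95)
  # permuted labels: all classifiers within chance band on a balanced set
  ds$y <- with_seed(17, sample(ds$y))
  rep2 <- run_baselines(ds, folds, seed = 5)
  expect_true(all(rep2$summary$mean >= 0.35 & rep2$summary$mean <= 0.65))
  # determinism
  rep3 <- run_baselines(ds, folds, seed = 5)
  expect_identical(rep2$per_fold, rep3$per_fold)
})
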