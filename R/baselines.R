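# Conventional machine-learning baselines applied to raw windows as flat
# feature vectors (no HRV extraction). Logistic regression and kNN use
# glmnet/FNN; the tree, random forest and linear SVM are compact in-package
# implementations (no CART/SVM package is available in this stack). Their
# role is comparative: on raw ECG these methods sit at chance, which is
# what the evaluation asserts.

BASELINE_NAMES <- c("decision_tree", "knn", "logistic_regression",
                    "random_forest", "svm")

# ---- CART-style tree with quantile candidate splits --------------------

cart_fit <- function(X, y, max_depth = 3L, min_leaf = 5L, n_quantiles = 4L,
                     mtry = NULL) {
  probs <- seq_len(n_quantiles) / (n_quantiles + 1)
  grow <- function(idx, depth) {
    yy <- y[idx]
    pred <- as.integer(mean(yy) >= 0.5)
    if (depth >= max_depth || length(idx) < 2L * min_leaf ||
        length(unique(yy)) == 1L)
      return(list(leaf = TRUE, pred = pred))
    feats <- if (is.null(mtry)) seq_len(ncol(X))
             else sample.int(ncol(X), min(mtry, ncol(X)))
    Xs <- X[idx, feats, drop = FALSE]
    n <- length(idx)
    pos <- yy == 1L
    best <- list(score = Inf)
    for (q in probs) {
      th <- apply(Xs, 2L, quantile, probs = q, names = FALSE)
      left <- sweep(Xs, 2L, th, "<=")
      nL <- colSums(left)
      posL <- colSums(left & pos)
      nR <- n - nL
      posR <- sum(pos) - posL
      ok <- nL >= min_leaf & nR >= min_leaf
      if (!any(ok)) next
      pL <- posL / pmax(nL, 1L)
      pR <- posR / pmax(nR, 1L)
      gini <- (nL * 2 * pL * (1 - pL) + nR * 2 * pR * (1 - pR)) / n
      gini[!ok] <- Inf
      j <- which.min(gini)
      if (gini[j] < best$score)
        best <- list(score = gini[j], feat = feats[j], th = th[j],
                     left_idx = idx[left[, j]], right_idx = idx[!left[, j]])
    }
    if (!is.finite(best$score)) return(list(leaf = TRUE, pred = pred))
    list(leaf = FALSE, feat = best$feat, th = best$th,
         left = grow(best$left_idx, depth + 1L),
         right = grow(best$right_idx, depth + 1L))
  }
  grow(seq_len(nrow(X)), 0L)
}

cart_predict <- function(tree, X) {
  out <- integer(nrow(X))
  route <- function(node, idx) {
    if (length(idx) == 0) return()
    if (node$leaf) {
      out[idx] <<- node$pred
      return()
    }
    goleft <- X[idx, node$feat] <= node$th
    route(node$left, idx[goleft])
    route(node$right, idx[!goleft])
  }
  route(tree, seq_len(nrow(X)))
  out
}

rf_fit_predict <- function(Xtr, ytr, Xte, n_trees = 25L) {
  mtry <- max(1L, floor(sqrt(ncol(Xtr))))
  votes <- matrix(0L, nrow(Xte), n_trees)
  for (b in seq_len(n_trees)) {
    rows <- sample.int(nrow(Xtr), replace = TRUE)
    tree <- cart_fit(Xtr[rows, , drop = FALSE], ytr[rows],
                     max_depth = 4L, mtry = mtry)
    votes[, b] <- cart_predict(tree, Xte)
  }
  as.integer(rowMeans(votes) >= 0.5)
}

# full-batch gradient descent on L2-regularized squared hinge loss
svm_fit_predict <- function(Xtr, ytr, Xte, iters = 150L, lr = 0.05) {
  ypm <- 2 * ytr - 1
  n <- nrow(Xtr)
  lambda <- 1 / n
  w <- numeric(ncol(Xtr))
  b <- 0
  for (it in seq_len(iters)) {
    margin <- ypm * (drop(Xtr %*% w) + b)
    viol <- pmax(0, 1 - margin)
    g <- -2 * viol * ypm / n
    dw <- drop(crossprod(Xtr, g)) + lambda * w
    db <- sum(g)
    w <- w - lr * dw
    b <- b - lr * db
  }
  as.integer(drop(Xte %*% w) + b > 0)
}

baseline_predict <- function(name, Xtr, ytr, Xte) {
  switch(name,
    logistic_regression = {
      fit <- glmnet::glmnet(Xtr, factor(ytr, levels = c(0, 1)),
                            family = "binomial", alpha = 0,
                            lambda = 1 / nrow(Xtr), standardize = FALSE)
      as.integer(drop(predict(fit, Xte, type = "response")) > 0.5)
    },
    knn = as.integer(as.character(
      FNN::knn(Xtr, Xte, factor(ytr, levels = c(0, 1)), k = 5))),
    decision_tree = cart_predict(cart_fit(Xtr, ytr), Xte),
    random_forest = rf_fit_predict(Xtr, ytr, Xte),
    svm = svm_fit_predict(Xtr, ytr, Xte),
    abort("unknown baseline '%s'", name))
}

#' Conventional baselines on raw windows
#'
#' Trains decision-tree, k-nearest-neighbor, logistic-regression,
#' random-forest and linear-SVM classifiers on raw normalized windows
#' (flattened, standardized per training fold) under the same subject-wise
#' fold plan as the network, and reports per-fold and aggregate accuracy.
#'
#' @param ds a `windowed_dataset`.
#' @param folds a [make_folds()] plan.
#' @param classifiers subset of
#'   `c("decision_tree", "knn", "logistic_regression", "random_forest",
#'   "svm")`.
#' @param seed integer seed (bootstrap/feature sampling).
#' @return object of class `baseline_report`: list with `per_fold`
#'   (classifier, fold, accuracy) and `summary` (mean/sd per classifier).
#' @export
run_baselines <- function(ds, folds, classifiers = BASELINE_NAMES,
                          seed = 1L) {
  if (!inherits(ds, "windowed_dataset")) abort("ds must be a windowed_dataset")
  if (!inherits(folds, "fold_plan")) abort("folds must be a fold_plan")
  classifiers <- match.arg(classifiers, BASELINE_NAMES, several.ok = TRUE)
  X <- t(ds$x)
  res <- data.frame()
  for (f in seq_len(folds$k)) {
    te <- ds$subject_id %in% folds$folds[[f]]
    Xtr <- X[!te, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    ytr <- ds$y[!te]
    yte <- ds$y[te]
    mu <- colMeans(Xtr)
    sg <- pmax(apply(Xtr, 2L, sd), 1e-8)
    Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sg, "/")
    Xte <- sweep(sweep(Xte, 2L, mu), 2L, sg, "/")
    for (cl in classifiers) {
      pred <- with_seed(derive_seed(seed, cl, f),
                        baseline_predict(cl, Xtr, ytr, Xte))
      res <- rbind(res, data.frame(classifier = cl, fold = f,
                                   accuracy = mean(pred == yte)))
    }
  }
  agg <- aggregate(accuracy ~ classifier, res,
                   function(a) c(mean = mean(a), sd = sd(a)))
  summary <- data.frame(classifier = agg$classifier,
                        mean = agg$accuracy[, "mean"],
                        sd = agg$accuracy[, "sd"])
  structure(list(per_fold = res, summary = summary),
            class = "baseline_report")
}

#' @export
print.baseline_report <- function(x, ...) {
  cat("<baseline_report>\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-20s %.3f (%.3f)\n", x$summary$classifier[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}
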