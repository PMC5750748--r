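#' Specify a predictive model
#'
#' @param kind `"svm_rbf"` (soft-margin SVM, Gaussian kernel, one-vs-one),
#'   `"complex_tree"` (deep CART tree with information-gain splitting), or
#'   `"knn1"` (1-nearest neighbour, Euclidean, ties broken by lowest
#'   training index).
#' @param svm_c SVM cost parameter (default 10).
#' @param svm_gamma RBF width, or `"auto"` for `1 / n_features` on
#'   standardized features.
#' @param tree_max_splits Maximum tree depth control (default 100 splits).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(kind = c("svm_rbf", "complex_tree", "knn1"),
                       svm_c = 10, svm_gamma = "auto", tree_max_splits = 100) {
  kind <- match.arg(kind)
  stopifnot(svm_c > 0, tree_max_splits >= 1)
  structure(list(kind = kind, svm_c = svm_c, svm_gamma = svm_gamma,
                 tree_max_splits = tree_max_splits),
            class = "model_spec")
}

fit_predict <- function(spec, x_train, y_train, x_test) {
  switch(spec$kind,
    svm_rbf = {
      gamma <- if (identical(spec$svm_gamma, "auto")) 1 / ncol(x_train)
               else spec$svm_gamma
      fit <- e1071::svm(x_train, y_train, kernel = "radial",
                        cost = spec$svm_c, gamma = gamma, scale = FALSE)
      predict(fit, x_test)
    },
    complex_tree = {
      df <- as.data.frame(x_train)
      names(df) <- paste0("f", seq_len(ncol(df)))
      df$.y <- y_train
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = "information"),
                          control = rpart::rpart.control(
                            minsplit = 2, cp = 0, xval = 0,
                            maxdepth = min(30, spec$tree_max_splits)))
      te <- as.data.frame(x_test)
      names(te) <- paste0("f", seq_len(ncol(te)))
      cls <- predict(fit, te, type = "class")
      factor(as.character(cls), levels = levels(y_train))
    },
    knn1 = knn1_predict(x_train, y_train, x_test),
    stop("unknown model kind")
  )
}

# 1-NN with deterministic lowest-index tie-break.
knn1_predict <- function(x_train, y_train, x_test) {
  tr2 <- rowSums(x_train^2)
  pred <- integer(nrow(x_test))
  for (i in seq_len(nrow(x_test))) {
    d2 <- tr2 - 2 * drop(x_train %*% x_test[i, ])
    pred[i] <- which.min(d2)                 # which.min takes the first min
  }
  y_train[pred]
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Splits samples into `k_folds` class-stratified folds (per-class fold
#' sizes differ by at most one), standardizes features with the training
#' folds' means and standard deviations only, fits the model on nine folds
#' and predicts the held-out fold, so every sample is validated exactly
#' once.
#'
#' @param features Numeric matrix or data frame, one row per sample.
#' @param labels Factor (or vector) of class labels.
#' @param model A [model_spec()].
#' @param k_folds Number of folds (default 10).
#' @param seed Integer seed fixing the fold assignment (and any model
#'   randomness).
#' @param standardize Standardize per training fold (default TRUE).
#' @return Object of class `cv_result`: `fold_assignment`, `predictions`,
#'   `confusion` (rows = true class), `per_class_sensitivity`,
#'   `per_class_specificity`, `total_accuracy` (all in percent), `model`.
#' @export
run_cv <- function(features, labels, model = model_spec("svm_rbf"),
                   k_folds = 10, seed = 1, standardize = TRUE) {
  x <- as.matrix(features)
  if (!all(is.finite(x))) stop("non-finite feature values")
  y <- factor(labels)
  if (any(table(y) < k_folds))
    stop("every class needs at least k_folds samples for stratified CV")
  folds <- with_seed(seed, stratified_folds(y, k_folds))
  preds <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    x_tr <- x[tr, , drop = FALSE]
    x_te <- x[!tr, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(x_tr)
      sg <- apply(x_tr, 2, sd)
      sg[sg < 1e-12] <- 1
      x_tr <- sweep(sweep(x_tr, 2, mu), 2, sg, "/")
      x_te <- sweep(sweep(x_te, 2, mu), 2, sg, "/")
    }
    preds[!tr] <- with_seed(derive_seed(seed, f),
                            fit_predict(model, x_tr, y[tr], x_te))
  }
  confusion <- table(truth = y, prediction = preds)
  met <- confusion_metrics(confusion)
  structure(list(fold_assignment = folds, predictions = preds,
                 confusion = confusion,
                 per_class_sensitivity = met$per_class_sensitivity,
                 per_class_specificity = met$per_class_specificity,
                 total_accuracy = met$total_accuracy,
                 model = model, k_folds = k_folds, seed = seed),
            class = "cv_result")
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold CV: total accuracy %.2f%%\n",
              x$model$kind, x$k_folds, x$total_accuracy))
  invisible(x)
}

#' Sensitivity, specificity, and accuracy from a confusion matrix
#'
#' Per class c: sensitivity = TP / (TP + FN) and specificity =
#' TN / (TN + FP), in percent; total accuracy is the trace over the total.
#' A class with no true samples has undefined sensitivity (`NA`).
#'
#' @param confusion Square nonnegative matrix, rows = true classes.
#' @return List `per_class_sensitivity`, `per_class_specificity` (percent,
#'   named), `total_accuracy` (percent).
#' @export
confusion_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn) * 100, NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp) * 100, NA_real_)
  names(sens) <- names(spec) <- rownames(cm)
  list(per_class_sensitivity = sens,
       per_class_specificity = spec,
       total_accuracy = sum(tp) / total * 100)
}

#' Principal-component reduction of a feature table
#'
#' Centres and unit-scales columns (constant columns are dropped with a
#' warning), eigendecomposes the covariance, and projects onto the leading
#' components. Loadings and per-feature contributions (squared loading as a
#' percentage of the component) are exposed for inspecting which features
#' drive each component.
#'
#' @param features Numeric matrix or data frame.
#' @param n_components Components to keep (default 10).
#' @return List with `model` (class `pca_model`: `components`,
#'   `explained_variance_ratio`, `loadings`, `contributions`, `n_kept`,
#'   `center`, `scale`, `kept_columns`) and `reduced` (samples x
#'   `n_components` score matrix).
#' @export
pca_reduce <- function(features, n_components = 10) {
  x <- as.matrix(features)
  stopifnot(nrow(x) > n_components)
  keep <- apply(x, 2, sd) > 1e-12
  if (!all(keep)) {
    warning(sum(!keep), " constant feature column(s) dropped")
    x <- x[, keep, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  n_components <- min(n_components, ncol(pc$rotation))
  contrib <- sweep(pc$rotation^2, 2, colSums(pc$rotation^2), "/") * 100
  model <- structure(list(
    components = pc$rotation[, seq_len(n_components), drop = FALSE],
    explained_variance_ratio = evr,
    loadings = pc$rotation,
    contributions = contrib,
    n_kept = n_components,
    center = pc$center, scale = pc$scale,
    kept_columns = which(keep)), class = "pca_model")
  list(model = model,
       reduced = pc$x[, seq_len(n_components), drop = FALSE])
}

#' One-tailed exact Wilcoxon signed-rank test
#'
#' Tests whether paired values in `acc_a` are stochastically larger than in
#' `acc_b`. Zero differences are dropped; ties in the absolute differences
#' receive midranks. For n <= 15 remaining pairs the null distribution is
#' enumerated exactly over all 2^n sign patterns; larger n uses the normal
#' approximation with tie correction.
#'
#' @param acc_a,acc_b Paired numeric vectors (e.g. per-participant
#'   accuracies of two methods), equal length.
#' @param exact_max Largest n for exact enumeration (default 15).
#' @return List `statistic` (W+), `p_value`, `confidence`
#'   (`(1 - p) * 100`, percent), `n_effective`.
#' @export
wilcoxon_onetailed <- function(acc_a, acc_b, exact_max = 15) {
  stopifnot(length(acc_a) == length(acc_b), length(acc_a) >= 5)
  d <- acc_a - acc_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p_value = 1, confidence = 0, n_effective = 0))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  if (n <= exact_max) {
    # Exact null: all 2^n equiprobable sign assignments of the ranks.
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p <- mean(w_all >= w_obs - 1e-9)
  } else {
    mu <- n * (n + 1) / 4
    sigma2 <- sum(r^2) / 4
    p <- stats::pnorm((w_obs - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  list(statistic = w_obs, p_value = p, confidence = (1 - p) * 100,
       n_effective = n)
}

#' Welch two-sample t-test with a rejection decision
#'
#' Two-sided Welch test of equal means, with rejection at level `alpha`.
#' Degenerate inputs (both samples constant with equal means) return
#' `t = 0`, `p = 1`, no rejection.
#'
#' @param acc_a,acc_b Numeric vectors, each of length >= 2.
#' @param alpha Significance level (default 0.005).
#' @return List `t`, `p_value`, `reject`.
#' @export
ttest_two_sample <- function(acc_a, acc_b, alpha = 0.005) {
  stopifnot(length(acc_a) >= 2, length(acc_b) >= 2)
  if (sd(acc_a) < 1e-12 && sd(acc_b) < 1e-12) {
    if (abs(mean(acc_a) - mean(acc_b)) < 1e-12)
      return(list(t = 0, p_value = 1, reject = FALSE))
  }
  tt <- tryCatch(t.test(acc_a, acc_b, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    # both samples essentially constant with unequal means
    return(list(t = sign(mean(acc_a) - mean(acc_b)) * Inf, p_value = 0,
                reject = TRUE))
  }
  list(t = unname(tt$statistic), p_value = tt$p.value,
       reject = tt$p.value < alpha)
}
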