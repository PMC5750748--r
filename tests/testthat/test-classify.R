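make_clusters <- function(n_per_class = 20, n_classes = 8, d = 12,
                          sep = 12, noise = 0.5, seed = 41) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(n_classes * d), n_classes) * sep
    x <- do.call(rbind, lapply(seq_len(n_classes), function(k)
      matrix(rnorm(n_per_class * d, sd = noise), n_per_class) +
        matrix(centers[k, ], n_per_class, d, byrow = TRUE)))
    list(x = x, y = factor(rep(paste0("c", seq_len(n_classes)),
                               each = n_per_class)))
  })
}

test_that("well-separated clusters are classified almost perfectly by all models", {
  dat <- make_clusters()
  for (kind in c("svm_rbf", "complex_tree", "knn1")) {
    cv <- run_cv(dat$x, dat$y, model_spec(kind), 10, seed = 1)
    expect_gte(cv$total_accuracy, 99)
  }
})

test_that("permuted labels drop accuracy to chance for 8 balanced classes", {
  dat <- make_clusters()
  yp <- withr::with_seed(99, sample(dat$y))
  cv <- run_cv(dat$x, yp, model_spec("knn1"), 10, seed = 1)
  expect_lt(abs(cv$total_accuracy - 12.5), 5 + 1e-9)
})

test_that("stratified folds balance classes and validate each sample once", {
  dat <- make_clusters(n_per_class = 23)
  cv <- run_cv(dat$x, dat$y, model_spec("knn1"), 10, seed = 7)
  expect_equal(sum(cv$confusion), length(dat$y))
  for (cl in levels(dat$y)) {
    sizes <- table(cv$fold_assignment[dat$y == cl])
    expect_lte(diff(range(sizes)), 1)
  }
  # same seed reproduces fold assignment and predictions exactly
  cv2 <- run_cv(dat$x, dat$y, model_spec("knn1"), 10, seed = 7)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_identical(cv$predictions, cv2$predictions)
  t1 <- run_cv(dat$x, dat$y, model_spec("complex_tree"), 5, seed = 7)
  t2 <- run_cv(dat$x, dat$y, model_spec("complex_tree"), 5, seed = 7)
  expect_identical(t1$predictions, t2$predictions)
  # class c5 has only 8 samples in the first 100 rows
  expect_error(run_cv(dat$x[1:100, ], dat$y[1:100], k_folds = 10),
               "at least k_folds")
})

test_that("confusion metrics match hand counts and are permutation-invariant", {
  d <- diag(c(5, 9, 3))
  m <- confusion_metrics(d)
  expect_true(all(m$per_class_sensitivity == 100))
  expect_true(all(m$per_class_specificity == 100))
  expect_equal(m$total_accuracy, 100)

  cm <- matrix(c(8, 1, 2, 9), 2)                # rows true: [[8,2],[1,9]]
  m2 <- confusion_metrics(cm)
  expect_equal(unname(m2$per_class_sensitivity[1]), 80)
  expect_equal(unname(m2$per_class_specificity[1]), 90)
  expect_equal(m2$total_accuracy, 85)

  set.seed(42)
  big <- matrix(rpois(16, 5), 4)
  p <- c(3, 1, 4, 2)
  m3 <- confusion_metrics(big)
  m4 <- confusion_metrics(big[p, p])
  expect_equal(unname(m3$per_class_sensitivity[p]),
               unname(m4$per_class_sensitivity))
  expect_equal(m3$total_accuracy, m4$total_accuracy)

  mz <- confusion_metrics(matrix(c(0, 3, 0, 5), 2))   # empty true class 1
  expect_true(is.na(mz$per_class_sensitivity[1]))
})

test_that("PCA keeps rank structure, satisfies the eigenvalue identity, defaults to 10", {
  set.seed(43)
  basis <- qr.Q(qr(matrix(rnorm(20 * 3), 20)))   # exact 3-dim subspace
  x <- matrix(rnorm(100 * 3), 100) %*% t(basis)
  red <- pca_reduce(x, 10)
  expect_equal(red$model$n_kept, 10)
  expect_lt(sum(red$model$explained_variance_ratio[4:20]), 1e-12)
  # components orthonormal
  g <- t(red$model$components) %*% red$model$components
  expect_lt(max(abs(g - diag(10))), 1e-9)
  expect_true(all(diff(red$model$explained_variance_ratio) < 1e-12))

  # back-projection error equals the discarded eigenvalue mass
  set.seed(44)
  xf <- matrix(rnorm(60 * 12), 60)
  k <- 5
  redf <- pca_reduce(xf, k)
  xs <- scale(xf)
  recon <- redf$reduced %*% t(redf$model$components)
  err <- sum((xs - recon)^2) / (nrow(xf) - 1)
  lam <- redf$model$explained_variance_ratio * 12
  expect_equal(err, sum(lam[(k + 1):12]), tolerance = 1e-9)

  xc <- cbind(xf, 3)                             # constant column dropped
  expect_warning(pca_reduce(xc, 5), "constant")
})

test_that("exact Wilcoxon signed-rank matches enumeration and the oracle", {
  a <- c(5, 6, 7, 8, 9, 10, 11, 12, 13, 14)
  b <- a - runif(10, 0.5, 1.5)                   # all positive differences
  res <- wilcoxon_onetailed(a, b)
  expect_equal(res$p_value, 1 / 1024, tolerance = 1e-12)
  expect_equal(res$confidence, (1 - 1 / 1024) * 100)

  expect_equal(wilcoxon_onetailed(a, a)$p_value, 1)
  expect_equal(wilcoxon_onetailed(a, a)$confidence, 0)

  # agreement with the reference implementation on tie-free data, n <= 8
  set.seed(45)
  for (n in 5:8) {
    for (rep in 1:5) {
      x <- round(rnorm(n), 6); y <- round(rnorm(n), 6)
      ref <- suppressWarnings(
        stats::wilcox.test(x, y, paired = TRUE, alternative = "greater",
                           exact = TRUE))$p.value
      expect_equal(wilcoxon_onetailed(x, y, exact_max = 15)$p_value, ref,
                   tolerance = 1e-12, label = paste("n =", n))
    }
  }
})

test_that("Welch t-test wrapper computes the closed form and rejects on separation", {
  expect_false(ttest_two_sample(c(1, 2, 3), c(1, 2, 3))$reject)

  set.seed(46)
  a <- rnorm(10, 0, 1); b <- rnorm(10, 10, 1)    # ~10 pooled SDs apart
  expect_true(ttest_two_sample(b, a, alpha = 0.005)$reject)

  # 3-point toy pair against the hand-computed Welch statistic
  x <- c(1, 2, 3); y <- c(2, 4, 9)
  tt <- ttest_two_sample(x, y)
  se <- sqrt(var(x) / 3 + var(y) / 3)
  expect_equal(tt$t, (mean(x) - mean(y)) / se, tolerance = 1e-12)

  expect_true(ttest_two_sample(c(1, 1), c(2, 2))$reject)
  expect_false(ttest_two_sample(c(2, 2), c(2, 2))$reject)
})

test_that("1-NN is invariant to duplicated feature columns without standardization", {
  dat <- make_clusters(n_per_class = 12, noise = 3)
  cv1 <- run_cv(dat$x, dat$y, model_spec("knn1"), 4, seed = 3,
                standardize = FALSE)
  cv2 <- run_cv(cbind(dat$x, dat$x), dat$y, model_spec("knn1"), 4, seed = 3,
                standardize = FALSE)
  expect_identical(cv1$predictions, cv2$predictions)
})

test_that("PCA-reduced CV matches raw CV on low-rank data", {
  set.seed(47)
  basis <- qr.Q(qr(matrix(rnorm(30 * 3), 30)))
  centers <- matrix(rnorm(8 * 3), 8) * 10
  scores <- do.call(rbind, lapply(1:8, function(k)
    matrix(rnorm(15 * 3), 15) + matrix(centers[k, ], 15, 3, byrow = TRUE)))
  x <- scores %*% t(basis)
  y <- factor(rep(1:8, each = 15))
  raw <- run_cv(x, y, model_spec("svm_rbf"), 10, seed = 2)$total_accuracy
  red <- pca_reduce(x, 5)$reduced
  prj <- run_cv(red, y, model_spec("svm_rbf"), 10, seed = 2)$total_accuracy
  expect_lte(abs(raw - prj), 2)
})
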