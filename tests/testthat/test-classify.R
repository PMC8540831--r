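test_that("stratified folds are balanced, disjoint and cover everything", {
  y <- rep(c("I", "II", "III", "IV"), each = 5)
  f <- stratified_kfold(y, k = 5, seed = 1)
  for (k in 1:5)
    expect_equal(unname(table(y[f == k])), rep(1L, 4), ignore_attr = TRUE)
  expect_setequal(unique(f), 1:5)
  expect_length(f, 20)

  # imbalanced labels: per-fold class counts within 1 of proportionality
  y2 <- rep(c("a", "b", "c"), times = c(23, 11, 7))
  f2 <- stratified_kfold(y2, k = 3, seed = 2)
  for (cl in c("a", "b", "c")) {
    counts <- table(factor(f2[y2 == cl], levels = 1:3))
    expect_lte(diff(range(counts)), 1)
  }
  expect_error(stratified_kfold(rep(c("a", "b"), c(10, 3)), k = 5), "at least")
  # deterministic per seed
  expect_identical(f, stratified_kfold(y, k = 5, seed = 1))
})

test_that("the hyper-parameter grid has decade steps and the tie-break order", {
  g <- svm_param_grid()
  expect_equal(sum(g$kernel == "radial"), 64)      # 8 gamma x 8 C
  expect_equal(sum(g$kernel == "sigmoid"), 64)
  expect_equal(sum(g$kernel == "polynomial"), 64 * 6)
  expect_equal(sort(unique(g$gamma)), 10^(-4:3))
  expect_equal(sort(unique(g$cost)), 10^(-3:4))
  # earlier rows are preferred on ties: C, then gamma, then degree, kernel
  expect_true(!is.unsorted(g$cost))
  first_c <- g[g$cost == min(g$cost), ]
  expect_true(!is.unsorted(first_c$gamma))
})

test_that("grid search finds a separating config and ignores sample order", {
  blobs <- make_blob_features(12, d = 4, shift = 5, seed = 3)
  keep <- blobs$y %in% c("I", "II")
  X <- scale(blobs$X[keep, ]); y <- droplevels(blobs$y[keep])
  gs <- grid_search_svm(X, y, grid = small_grid(), seed = 5)
  expect_equal(gs$accuracy, 1)

  perm <- withr::with_seed(6, sample(nrow(X)))
  gs2 <- grid_search_svm(X[perm, ], y[perm], grid = small_grid(), seed = 5)
  expect_identical(gs$config, gs2$config)
  expect_error(grid_search_svm(X, rep("I", nrow(X)), small_grid()),
               "single class")
})

test_that("one-against-all SVM recovers well-separated classes", {
  blobs <- make_blob_features(15, d = 5, shift = 5, seed = 4)
  X <- scale(blobs$X)
  m <- oaa_svm_fit(X, blobs$y,
                   list(kernel = "radial", gamma = 0.1, cost = 10,
                        degree = 3))
  p <- oaa_svm_predict(m, X)
  expect_gte(mean(p$class == blobs$y), 0.95)
  expect_equal(dim(p$scores), c(60L, 4L))
  expect_equal(colnames(p$scores), levels(blobs$y))
})

test_that("cross-validation separates class-shifted Gaussians and is deterministic", {
  blobs <- make_blob_features(50, d = 6, shift = 4, seed = 5)  # n = 200
  r <- cross_validate(blobs$X, blobs$y, k = 5, seed = 9, grid = small_grid())
  expect_gte(r$accuracy, 0.95)

  # every sample predicted exactly once across folds
  expect_equal(sort(unique(r$fold)), 1:5)
  expect_equal(sum(r$confusion), 200)
  # pooled accuracy is the fold-size-weighted mean of per-fold accuracies
  sizes <- tabulate(r$fold, 5)
  expect_equal(r$accuracy, sum(r$per_fold_accuracy * sizes) / sum(sizes),
               tolerance = 1e-12)

  r2 <- cross_validate(blobs$X, blobs$y, k = 5, seed = 9, grid = small_grid())
  expect_identical(r$confusion, r2$confusion)
  expect_identical(r$per_fold_accuracy, r2$per_fold_accuracy)
})

test_that("wide feature blocks can be replaced by their Gram factor exactly", {
  withr::local_seed(44)
  X <- matrix(rnorm(40 * 300), 40, 300)
  y <- factor(rep(c("I", "II"), each = 20))
  z <- densitex:::.gram_factor(X[1:30, ], X[31:40, ])
  cfg <- list(kernel = "radial", gamma = 0.01, cost = 1, degree = 3)
  p_raw <- oaa_svm_predict(oaa_svm_fit(X[1:30, ], y[1:30], cfg), X[31:40, ])
  p_z <- oaa_svm_predict(oaa_svm_fit(z$train, y[1:30], cfg), z$test)
  expect_equal(p_raw$scores, p_z$scores, tolerance = 1e-8)
  expect_identical(p_raw$class, p_z$class)
})

test_that("metrics reproduce the published worked examples", {
  ref <- reference_confusion_matrices()
  acc1 <- function(cm) round(100 * compute_metrics(cm)$accuracy, 1)
  expect_equal(acc1(ref$iso_mlbp), 84.6)
  expect_equal(acc1(ref$iso), 73.8)
  expect_equal(acc1(ref$max), 63.3)
  expect_equal(acc1(ref$in_min), 59.7)
  expect_equal(acc1(ref$sum), 55.3)
  expect_equal(acc1(ref$lbp), 70.9)
  expect_equal(acc1(ref$elbp), 72.1)
  expect_equal(acc1(ref$mlbp), 73.3)
  expect_equal(acc1(ref$max_mlbp), 81.4)
  expect_equal(acc1(ref$in_min_mlbp), 76.8)
  expect_equal(acc1(ref$sum_mlbp), 68.9)
  expect_equal(acc1(ref$binary_mlbp), 91.9)
  expect_equal(acc1(ref$binary_iso), 89.2)
  expect_equal(acc1(ref$binary_iso_mlbp), 92.9)
})

test_that("kappa, F1 and AUC match independent oracles", {
  d <- diag(c(5, 3, 2))
  m <- compute_metrics(d)
  expect_equal(m$accuracy, 1)
  expect_equal(m$kappa, 1)
  expect_equal(m$f1_weighted, 1)

  withr::local_seed(45)
  for (i in 1:5) {
    cm <- matrix(sample(0:9, 16, replace = TRUE), 4, 4)
    if (sum(cm) == 0) next
    expect_equal(compute_metrics(cm)$kappa, oracle_kappa(cm),
                 tolerance = 1e-12)
  }
  expect_error(compute_metrics(matrix(0, 2, 2)), "empty")

  # rank-statistic AUC vs exhaustive pair counting (with ties)
  for (i in 1:5) {
    sc <- sample(seq(0, 1, 0.1), 20, replace = TRUE)
    pos <- runif(20) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(densitex:::.auc_binary(sc, pos), oracle_auc(sc, pos),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to permuting the sample order", {
  withr::local_seed(46)
  y <- factor(sample(c("I", "II", "III", "IV"), 60, replace = TRUE))
  p <- factor(sample(c("I", "II", "III", "IV"), 60, replace = TRUE),
              levels = levels(y))
  m1 <- compute_metrics(table(y, p))
  o <- sample(60)
  m2 <- compute_metrics(table(y[o], p[o]))
  expect_equal(m1, m2)
})

test_that("the paired t-test follows the textbook formula and edge contracts", {
  expect_equal(paired_ttest(c(0.7, 0.8, 0.9), c(0.7, 0.8, 0.9)), 1)
  expect_equal(paired_ttest(rep(0.8, 5), rep(0.7, 5)), 0)
  withr::local_seed(47)
  for (i in 1:5) {
    a <- runif(5); b <- runif(5)
    expect_equal(paired_ttest(a, b), oracle_paired_t_p(a, b),
                 tolerance = 1e-6)
  }
  expect_error(paired_ttest(1, 1), "length")
})

test_that("BI-RADS labels collapse to the low/high convention", {
  expect_equal(as.character(binarize_labels(c("I", "II", "III", "IV"))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(binarize_labels(rep("I", 3))), rep("low", 3))
  sizes <- reference_class_sizes()
  b <- binarize_labels(rep(names(sizes), times = sizes))
  expect_equal(unname(table(b)), c(282L, 127L), ignore_attr = TRUE)
  expect_error(binarize_labels(c("I", "V")), "unknown")
})
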