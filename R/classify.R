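#' Stratified k-fold assignment
#'
#' Shuffles each class independently (seeded) and deals its members
#' round-robin across folds, so per-fold class counts differ from exact
#' proportionality by at most one sample. Class offsets are rotated so total
#' fold sizes stay balanced.
#'
#' @param labels vector of class labels.
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @return integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  k <- as.integer(k)
  tab <- table(labels)
  if (any(tab < k))
    stop("every class needs at least k members for stratified k-fold",
         call. = FALSE)
  fold <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  fold
}

#' SVM hyper-parameter grid
#'
#' Decade steps across the search ranges `gamma` in `[1e-4, 1e3]` and `C` in
#' `[1e-3, 1e4]`, kernels RBF / polynomial / sigmoid, degree 1--6 for the
#' polynomial kernel only. Rows are ordered so that the tie-break for equal
#' cross-validated accuracy is: smaller C, then smaller gamma, then lower
#' degree, then kernel order RBF < Poly < Sigmoid.
#'
#' @param kernels subset of `c("radial", "polynomial", "sigmoid")`.
#' @param gamma,cost candidate values.
#' @param degrees polynomial degrees.
#' @return data frame with columns kernel, gamma, cost, degree.
#' @export
svm_param_grid <- function(kernels = c("radial", "polynomial", "sigmoid"),
                           gamma = 10^(-4:3), cost = 10^(-3:4),
                           degrees = 1:6) {
  kernels <- match.arg(kernels, several.ok = TRUE)
  parts <- lapply(kernels, function(kn) {
    dg <- if (kn == "polynomial") degrees else 1L
    expand.grid(kernel = kn, gamma = gamma, cost = cost, degree = dg,
                stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, parts)
  krank <- match(g$kernel, c("radial", "polynomial", "sigmoid"))
  g[order(g$cost, g$gamma, g$degree, krank), , drop = FALSE]
}

# ---- one-against-all SVM -------------------------------------------------

#' Fit a one-against-all multiclass SVM
#'
#' One binary C-SVM (libsvm via e1071) per class against the rest; a sample
#' is assigned to the class with the largest decision value. Features are
#' used as passed (standardize on training statistics beforehand).
#'
#' @param X numeric training matrix.
#' @param y training labels (factor or coercible).
#' @param config one row of [svm_param_grid()] (list-like with kernel,
#'   gamma, cost, degree).
#' @return an `oaa_svm` model.
#' @export
oaa_svm_fit <- function(X, y, config) {
  y <- as.factor(y)
  lv <- levels(droplevels(y))
  if (length(lv) < 2L)
    stop("training data contains a single class", call. = FALSE)
  models <- lapply(lv, function(cl) {
    yb <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
    e1071::svm(X, yb, scale = FALSE, kernel = config$kernel,
               gamma = config$gamma, cost = config$cost,
               degree = config$degree, fitted = FALSE)
  })
  structure(list(models = models, classes = lv, config = config),
            class = "oaa_svm")
}

#' Predict with a one-against-all SVM
#' @param model an [oaa_svm_fit()] model.
#' @param X numeric matrix.
#' @return list with `class` (factor) and `scores` (n x k decision-value
#'   matrix, columns named by class).
#' @export
oaa_svm_predict <- function(model, X) {
  scores <- vapply(model$models, function(m) {
    dv <- attr(stats::predict(m, X, decision.values = TRUE),
               "decision.values")
    # orient so larger = more "pos", whatever pair order libsvm chose
    if (colnames(dv)[1L] == "rest/pos") -dv[, 1L] else dv[, 1L]
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X),
                   dimnames = list(NULL, model$classes))
  cls <- factor(model$classes[max.col(scores, ties.method = "first")],
                levels = model$classes)
  list(class = cls, scores = scores)
}

#' Grid-search SVM hyper-parameters by inner cross-validation
#'
#' Exhaustively evaluates every grid row by stratified `inner_k`-fold
#' accuracy of the one-against-all SVM on the training portion and returns
#' the best configuration (first row wins ties, i.e. the grid's tie-break
#' order applies). Deterministic per seed and invariant to sample order.
#'
#' @param X standardized training features.
#' @param y training labels.
#' @param grid a [svm_param_grid()].
#' @param inner_k inner folds (default 3).
#' @param seed RNG seed for the inner fold split.
#' @return list with `config` (the best row, as a list with kernel, gamma,
#'   cost, degree), `accuracy` (its inner-CV accuracy) and `accuracies`
#'   (per grid row).
#' @export
grid_search_svm <- function(X, y, grid = svm_param_grid(), inner_k = 3L,
                            seed = 1L) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop("training data contains a single class", call. = FALSE)
  # order-invariant inner split: process samples in a canonical order
  ord <- order(as.integer(y), apply(as.matrix(X), 1L, function(r)
    sum(r * seq_along(r))))
  Xo <- as.matrix(X)[ord, , drop = FALSE]
  yo <- y[ord]
  fold <- stratified_kfold(yo, k = inner_k, seed = seed)
  lv <- levels(yo)
  # hot loop below runs nrow(grid) * inner_k * nlevels svm fits: hoist all
  # per-fold data (subsets, one-vs-rest factors) out of it
  splits <- lapply(seq_len(inner_k), function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    list(Xtr = Xo[tr, , drop = FALSE], Xte = Xo[te, , drop = FALSE],
         yte = yo[te],
         ybins = lapply(lv, function(cl)
           factor(ifelse(yo[tr] == cl, "pos", "rest"),
                  levels = c("pos", "rest"))))
  })
  kern <- as.character(grid$kernel)
  gam <- grid$gamma; cst <- grid$cost; dgr <- grid$degree
  n_total <- length(yo)
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    correct <- 0L
    for (s in splits) {
      scores <- matrix(0, nrow(s$Xte), length(lv))
      for (ci in seq_along(lv)) {
        m <- e1071::svm(s$Xtr, s$ybins[[ci]], scale = FALSE,
                        kernel = kern[i], gamma = gam[i], cost = cst[i],
                        degree = dgr[i], fitted = FALSE)
        dv <- attr(stats::predict(m, s$Xte, decision.values = TRUE),
                   "decision.values")
        scores[, ci] <- if (colnames(dv)[1L] == "rest/pos") -dv[, 1L]
                        else dv[, 1L]
      }
      pred <- lv[max.col(scores, ties.method = "first")]
      correct <- correct + sum(pred == s$yte)
    }
    acc[i] <- correct / n_total
  }
  best <- which.max(acc)
  list(config = as.list(grid[best, ]), accuracy = acc[best],
       accuracies = acc)
}

# ---- cross-validated evaluation ------------------------------------------

#' Cross-validated descriptor evaluation
#'
#' Stratified k-fold cross-validation of the one-against-all SVM. Per outer
#' fold, strictly on training data only: feature standardization, optional
#' dimensionality reduction (PCA projection or autoencoder bottleneck) and
#' the hyper-parameter grid search; the held-out fold is then transformed
#' with the training-fold statistics and predicted. Test predictions are
#' pooled into one confusion matrix.
#'
#' @param X numeric feature matrix (M x N).
#' @param y class labels.
#' @param k outer folds (default 5).
#' @param seed RNG seed controlling all fold splits.
#' @param selector `"none"`, `"pca"` or `"autoencoder"`.
#' @param n_components PCA components kept when `selector = "pca"`.
#' @param ae_spec an [autoencoder_spec()] when `selector = "autoencoder"`
#'   (its `input_dim` must match `ncol(X)`).
#' @param grid hyper-parameter grid for [grid_search_svm()].
#' @param inner_k inner folds of the grid search.
#' @return a `cv_result`: `per_fold_accuracy`, `confusion` (pooled, rows =
#'   actual), `accuracy`, `auc_mean`, `auc_sd`, `per_fold_auc`, `kappa`,
#'   `f1_weighted`, `f1_macro`, `best_configs` (one per fold), `fold`.
#' @export
cross_validate <- function(X, y, k = 5L, seed = 1L,
                           selector = c("none", "pca", "autoencoder"),
                           n_components = 45L, ae_spec = NULL,
                           grid = svm_param_grid(), inner_k = 3L) {
  selector <- match.arg(selector)
  X <- as.matrix(X)
  y <- as.factor(y)
  fold <- stratified_kfold(y, k = k, seed = seed)
  lv <- levels(y)
  pooled_pred <- factor(rep(lv[1L], length(y)), levels = lv)
  per_acc <- numeric(k)
  per_auc <- rep(NA_real_, k)
  best_configs <- vector("list", k)

  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sd_ <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sd_[sd_ == 0] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sd_, "/")
    Zte <- sweep(sweep(X[te, , drop = FALSE], 2L, mu), 2L, sd_, "/")

    if (selector == "pca") {
      pm <- fit_pca(Ztr)
      n_use <- min(n_components, ncol(Ztr))
      Ztr <- project_pca(pm, Ztr, n_use)
      Zte <- project_pca(pm, Zte, n_use)
    } else if (selector == "autoencoder") {
      if (is.null(ae_spec))
        stop("ae_spec required for the autoencoder selector", call. = FALSE)
      enc <- train_autoencoder(Ztr, ae_spec)
      Ztr <- encode(enc, Ztr)
      Zte <- encode(enc, Zte)
    }

    if (ncol(Ztr) > nrow(Ztr)) {
      z <- .gram_factor(Ztr, Zte)
      Ztr <- z$train; Zte <- z$test
    }

    gs <- grid_search_svm(Ztr, y[tr], grid = grid, inner_k = inner_k,
                          seed = seed + f)
    best_configs[[f]] <- gs$config
    m <- oaa_svm_fit(Ztr, y[tr], gs$config)
    pr <- oaa_svm_predict(m, Zte)
    pooled_pred[te] <- pr$class
    per_acc[f] <- mean(pr$class == y[te])
    per_auc[f] <- macro_ovr_auc(pr$scores, y[te])
  }

  cm <- table(actual = y, predicted = pooled_pred)
  met <- compute_metrics(cm)
  structure(list(per_fold_accuracy = per_acc, confusion = cm,
                 accuracy = met$accuracy,
                 auc_mean = mean(per_auc, na.rm = TRUE),
                 auc_sd = stats::sd(per_auc, na.rm = TRUE),
                 per_fold_auc = per_auc,
                 kappa = met$kappa, f1_weighted = met$f1_weighted,
                 f1_macro = met$f1_macro,
                 best_configs = best_configs, fold = fold,
                 labels = y, predictions = pooled_pred),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> accuracy %.1f%%, AUC %.1f +/- %.1f%%, kappa %.2f, F1(w) %.2f\n",
    100 * x$accuracy, 100 * x$auc_mean, 100 * x$auc_sd, x$kappa,
    x$f1_weighted))
  print(x$confusion)
  invisible(x)
}

# Exact kernel-preserving reparameterization for wide folds: the RBF,
# polynomial and sigmoid kernels depend on the data only through inner
# products, so replacing the fold's feature block by an eigenfactor Z of its
# Gram matrix (Z Z' = X X') leaves every kernel value -- and hence every SVM
# solution -- unchanged while capping the feature count at the fold's sample
# count. Purely computational; no statistical effect.
.gram_factor <- function(Xtr, Xte) {
  A <- rbind(Xtr, Xte)
  G <- tcrossprod(A)
  e <- eigen(G, symmetric = TRUE)
  Z <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(A))
  list(train = Z[seq_len(nrow(Xtr)), , drop = FALSE],
       test = Z[nrow(Xtr) + seq_len(nrow(Xte)), , drop = FALSE])
}

# ---- metrics -------------------------------------------------------------

# Binary AUC by the rank (Mann-Whitney) statistic; ties get 0.5 credit.
.auc_binary <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro one-vs-rest AUC from decision scores
#'
#' Mean over classes (present in `y`) of the binary AUC of that class's
#' decision score against all others.
#'
#' @param scores n x k matrix of per-class decision values, columns named by
#'   class.
#' @param y true labels.
#' @return macro-averaged AUC in `[0, 1]` (NA if no class is separable).
#' @export
macro_ovr_auc <- function(scores, y) {
  y <- as.character(y)
  aucs <- vapply(colnames(scores), function(cl)
    .auc_binary(scores[, cl], y == cl), numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy (trace/total), Cohen's kappa from the marginals, and per-class
#' F1 aggregated two ways: weighted by class support and macro-averaged.
#' AUC needs decision scores and is computed per fold inside
#' [cross_validate()].
#'
#' @param cm k x k confusion matrix, rows = actual, columns = predicted.
#' @return list: `accuracy`, `kappa`, `f1_weighted`, `f1_macro`,
#'   `per_class_f1`.
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(unclass(cm))
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square",
                                 call. = FALSE)
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  prec <- diag(cm) / colSums(cm)
  rec <- diag(cm) / rowSums(cm)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  f1[is.na(f1)] <- 0
  support <- rowSums(cm)
  list(accuracy = po, kappa = kappa,
       f1_weighted = sum(f1 * support) / total,
       f1_macro = mean(f1), per_class_f1 = f1)
}

#' Paired two-tailed t-test on fold-wise accuracies
#'
#' Degenerate cases are defined by contract: all-zero differences give
#' `p = 1`; zero-variance differences with a non-zero mean give `p = 0`.
#'
#' @param acc_a,acc_b equal-length paired accuracy vectors (length >= 2).
#' @return the two-tailed p-value.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 2L)
    stop("need equal-length paired samples of length >= 2", call. = FALSE)
  d <- acc_a - acc_b
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0) return(0)
  stats::t.test(acc_a, acc_b, paired = TRUE)$p.value
}

#' Collapse BI-RADS categories to binary density labels
#'
#' Low density (fatty and sparsely dense: BI-RADS I and II) versus high
#' density (heterogeneously and extremely dense: BI-RADS III and IV).
#'
#' @param labels vector with values in `I, II, III, IV`.
#' @return factor with levels `low`, `high`.
#' @export
binarize_labels <- function(labels) {
  lab <- as.character(labels)
  bad <- !(lab %in% c("I", "II", "III", "IV"))
  if (any(bad))
    stop("unknown BI-RADS label: ", paste(unique(lab[bad]), collapse = ", "),
         call. = FALSE)
  factor(ifelse(lab %in% c("I", "II"), "low", "high"),
         levels = c("low", "high"))
}
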