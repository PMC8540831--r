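#' Concatenate a multi-fractal block with an LBP block
#'
#' Fixed order: multi-fractal (alpha-histogram) block first, LBP-family
#' block second. A 100-bin alpha-histogram fused with the 512-length MLBP
#' descriptor yields the 612-bin cascaded descriptor.
#'
#' @param mf numeric vector (alpha-histogram block).
#' @param lbp numeric vector (LBP-family block).
#' @return numeric vector of length `length(mf) + length(lbp)`, values
#'   unchanged.
#' @export
concatenate_descriptors <- function(mf, lbp) {
  if (!is.numeric(mf) || length(mf) == 0L ||
      !is.numeric(lbp) || length(lbp) == 0L)
    stop("both descriptor blocks must be non-empty numeric vectors",
         call. = FALSE)
  c(mf, lbp)
}

#' Fit a PCA model
#'
#' Sample covariance (denominator `M - 1`) of the feature matrix, symmetric
#' eigendecomposition, eigenvalues sorted descending, and a deterministic
#' sign convention (the largest-magnitude entry of each eigenvector is made
#' positive).
#'
#' @param X numeric matrix, M samples x N features, M >= 2, no missing
#'   values.
#' @return a `pca_model`: `means`, `covariance`, `eigenvalues` (descending),
#'   `components` (eigenvectors in columns).
#' @export
fit_pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need M >= 2 samples to fit PCA", call. = FALSE)
  if (any(!is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  mu <- colMeans(X)
  CM <- stats::cov(X)
  eig <- eigen(CM, symmetric = TRUE)   # eigen() already sorts descending
  V <- eig$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(means = mu, covariance = CM,
                 eigenvalues = eig$values, components = V),
            class = "pca_model")
}

#' Project features onto the leading principal axes
#'
#' Centres `X` by the model means and projects onto the first `n`
#' eigenvectors; output columns are ordered by descending eigenvalue.
#'
#' @param model a [fit_pca()] model.
#' @param X numeric matrix with the model's feature count.
#' @param n number of components, `1 <= n <= N`.
#' @return M x n numeric matrix.
#' @export
project_pca <- function(model, X, n) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  N <- length(model$means)
  if (ncol(X) != N) stop("feature count mismatch with the PCA model",
                         call. = FALSE)
  if (n < 1L || n > N) stop("n out of range [1, N]", call. = FALSE)
  Xc <- sweep(X, 2L, model$means)
  Xc %*% model$components[, seq_len(n), drop = FALSE]
}

#' Choose the PCA component count by cross-validated accuracy
#'
#' Scans candidate component counts and returns the one whose stratified
#' cross-validated OAA-SVM accuracy is highest (ties go to the smaller
#' count). This mirrors how the fused descriptor's working dimensionality
#' (e.g. 45 of 612) is selected.
#'
#' @param X feature matrix (M x N).
#' @param y class labels.
#' @param candidates component counts to scan.
#' @param k,seed,grid passed to [cross_validate()].
#' @return list with `n` (chosen count) and `accuracies` (named vector).
#' @export
select_pca_n <- function(X, y, candidates = seq(5L, 70L, by = 5L), k = 5L,
                         seed = 1L, grid = svm_param_grid()) {
  candidates <- candidates[candidates <= ncol(X)]
  acc <- vapply(candidates, function(n) {
    cross_validate(X, y, k = k, seed = seed, selector = "pca",
                   n_components = n, grid = grid)$accuracy
  }, numeric(1))
  names(acc) <- candidates
  list(n = candidates[which.max(acc)], accuracies = acc)
}

#' Save / load a PCA model as JSON
#' @param model a `pca_model`.
#' @param path destination `.json`.
#' @return `path` invisibly, or the restored model for `read_pca_model()`.
#' @export
write_pca_model <- function(model, path) {
  jsonlite::write_json(
    list(means = model$means, eigenvalues = model$eigenvalues,
         components = model$components),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  V <- as.matrix(o$components)
  structure(list(means = o$means, covariance = NULL,
                 eigenvalues = o$eigenvalues, components = V),
            class = "pca_model")
}
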