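# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity with scalar loops / textbook formulas so they
# share no code path with the package's vectorized implementations.

# symmetric reflection of a scalar 1-based index into 1..n
refl1 <- function(i, n) {
  if (n == 1) return(1)
  j <- (i - 1) %% (2 * n)
  if (j < 0) j <- j + 2 * n
  if (j < n) j + 1 else 2 * n - j
}

# per-pixel window scan for the four multi-fractal measures
oracle_measure_map <- function(x, w, measure, tau = 1 / 255) {
  r <- (w - 1) / 2
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- numeric(0)
    for (di in -r:r) for (dj in -r:r)
      vals <- c(vals, x[refl1(i + di, H), refl1(j + dj, W)])
    out[i, j] <- switch(measure,
      maximum = max(vals),
      inverse_minimum = 1 - min(vals),
      summation = sum(vals),
      iso = sum(abs(vals - x[i, j]) <= tau))
  }
  out
}

# scalar bilinear sample with symmetric reflection (snaps near-integers the
# same way the implementation contract states)
oracle_bilinear <- function(x, rr, cc) {
  H <- nrow(x); W <- ncol(x)
  if (abs(rr - round(rr)) < 1e-9) rr <- round(rr)
  if (abs(cc - round(cc)) < 1e-9) cc <- round(cc)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  g <- function(a, b) x[refl1(a, H), refl1(b, W)]
  (1 - fr) * (1 - fc) * g(r0, c0) + (1 - fr) * fc * g(r0, c0 + 1) +
    fr * (1 - fc) * g(r0 + 1, c0) + fr * fc * g(r0 + 1, c0 + 1)
}

# per-pixel LBP/ELBP codes: neighbour i at angle 2*pi*i/P starting east,
# counter-clockwise; bit i weighted 2^i; s(x >= 0) = 1
oracle_code_map <- function(x, P, r_row, r_col) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    code <- 0
    for (b in 0:(P - 1)) {
      th <- 2 * pi * b / P
      gi <- oracle_bilinear(x, i - r_row * sin(th), j + r_col * cos(th))
      if (gi - x[i, j] >= -1e-12) code <- code + 2^b
    }
    out[i, j] <- code
  }
  out
}

# direct tally histogram over a mask
oracle_code_histogram <- function(codes, mask, P) {
  v <- codes[mask]
  counts <- vapply(0:(2^P - 1), function(k) sum(v == k), numeric(1))
  counts / length(v)
}

oracle_median3 <- function(x) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- numeric(0)
    for (di in -1:1) for (dj in -1:1)
      vals <- c(vals, x[refl1(i + di, H), refl1(j + dj, W)])
    out[i, j] <- median(vals)
  }
  out
}

# least-squares slope/intercept on (log w, log mu) for one pixel
oracle_loglog_fit <- function(mu, w) {
  fit <- lm(log(mu) ~ log(w))
  unname(coef(fit))  # (intercept, slope)
}

oracle_kappa <- function(cm) {
  total <- sum(cm)
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  (po - pe) / (1 - pe)
}

# textbook paired t-test with the t CDF
oracle_paired_t_p <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  2 * pt(-abs(t), df = n - 1)
}

# Wilcoxon/rank AUC, ties counted half
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# a tiny well-separated 4-class Gaussian feature set
make_blob_features <- function(n_per_class, d = 6, shift = 4, seed = 1) {
  withr::with_seed(seed, {
    k <- 4
    X <- matrix(rnorm(n_per_class * k * d), n_per_class * k, d)
    y <- factor(rep(c("I", "II", "III", "IV"), each = n_per_class))
    for (i in seq_len(k)) {
      rows <- ((i - 1) * n_per_class + 1):(i * n_per_class)
      X[rows, ] <- X[rows, ] +
        matrix(shift * sin(i * seq_len(d)), length(rows), d, byrow = TRUE)
    }
    list(X = X, y = y)
  })
}

# small RBF-only grid for tests that exercise CV mechanics, not grid breadth
small_grid <- function() {
  svm_param_grid(kernels = "radial", gamma = 10^(-2:0), cost = 10^(0:2))
}
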