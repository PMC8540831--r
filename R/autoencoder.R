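#' Autoencoder architecture specification
#'
#' A symmetric fully connected hourglass: the encoder narrows the input to
#' the code (bottleneck) layer, the decoder mirrors it back. With
#' `n_hidden_layers = 2m + 1` hidden layers the middle one is the code
#' layer. Intermediate widths interpolate geometrically between `input_dim`
#' and `code_dim`. Hidden activations are ReLU; the output layer is sigmoid
#' (binary cross-entropy reconstruction loss requires inputs scaled to
#' `[0, 1]`).
#'
#' @param input_dim feature count of the data.
#' @param n_hidden_layers odd count of hidden layers (5, 7, 9, 11, 13, 15).
#' @param code_dim bottleneck width (16, 32, 64 or 128 in the scanned
#'   configurations; any positive value < `input_dim` is accepted).
#' @param epochs,learning_rate,batch_size Adam training settings.
#' @param seed RNG seed for init and batch shuffling.
#' @return an `ae_spec` list including the full `layer_widths`.
#' @export
autoencoder_spec <- function(input_dim, n_hidden_layers = 11L, code_dim = 64L,
                             epochs = 200L, learning_rate = 1e-3,
                             batch_size = 32L, seed = 1L) {
  n_hidden_layers <- as.integer(n_hidden_layers)
  code_dim <- as.integer(code_dim)
  input_dim <- as.integer(input_dim)
  if (n_hidden_layers %% 2L == 0L || n_hidden_layers < 3L)
    stop("n_hidden_layers must be odd and >= 3", call. = FALSE)
  if (code_dim >= input_dim || code_dim < 1L)
    stop("code_dim must be in [1, input_dim)", call. = FALSE)
  m <- (n_hidden_layers - 1L) %/% 2L
  # geometric interpolation input -> code over m+1 steps, forced strictly
  # decreasing
  enc <- round(input_dim * (code_dim / input_dim)^(seq_len(m) / (m + 1L)))
  for (i in seq_along(enc)) {
    hi <- if (i == 1L) input_dim else enc[i - 1L]
    enc[i] <- max(min(enc[i], hi - 1L), code_dim + (m - i) + 1L)
  }
  widths <- c(input_dim, enc, code_dim, rev(enc), input_dim)
  structure(list(input_dim = input_dim, n_hidden_layers = n_hidden_layers,
                 code_dim = code_dim, layer_widths = as.integer(widths),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "ae_spec")
}

#' Build (initialize) an autoencoder network
#'
#' He-initialized weights for every consecutive layer pair, zero biases.
#'
#' @param spec an [autoencoder_spec()].
#' @return an `ae_net` list: `W` (list of weight matrices), `b` (biases),
#'   `spec`.
#' @export
build_autoencoder <- function(spec) {
  stopifnot(inherits(spec, "ae_spec"))
  widths <- spec$layer_widths
  withr::with_seed(spec$seed, {
    W <- list(); b <- list()
    for (i in seq_len(length(widths) - 1L)) {
      fan_in <- widths[i]
      W[[i]] <- matrix(stats::rnorm(fan_in * widths[i + 1L],
                                    sd = sqrt(2 / fan_in)),
                       fan_in, widths[i + 1L])
      b[[i]] <- rep(0, widths[i + 1L])
    }
    structure(list(W = W, b = b, spec = spec), class = "ae_net")
  })
}

#' Total trainable parameter count of a network
#' @param net an `ae_net` (or an `ae_spec`, counted from its widths).
#' @return integer parameter count (weights + biases).
#' @export
n_parameters <- function(net) {
  widths <- if (inherits(net, "ae_spec")) net$layer_widths
            else net$spec$layer_widths
  sum(widths[-length(widths)] * widths[-1L]) + sum(widths[-1L])
}

#' Train an autoencoder and keep the encoder
#'
#' Features are min-max scaled to `[0, 1]` per column (constant columns map
#' to 0), then the network is trained to reconstruct them under binary
#' cross-entropy with Adam. Deterministic per spec seed. The decoder is
#' discarded; the returned encoder carries the scaling so [encode()] can be
#' applied to new data.
#'
#' @param X numeric matrix, M samples x `input_dim` features.
#' @param spec an [autoencoder_spec()].
#' @return an `ae_encoder`: encoder weights, scaling parameters,
#'   `loss_history` (mean BCE per epoch).
#' @export
train_autoencoder <- function(X, spec) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  if (ncol(X) != spec$input_dim)
    stop("ncol(X) must equal spec$input_dim", call. = FALSE)
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  rngv <- ifelse(hi > lo, hi - lo, 1)
  S <- sweep(sweep(X, 2L, lo), 2L, rngv, "/")

  net <- build_autoencoder(spec)
  W <- net$W; b <- net$b
  L <- length(W)
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; epsb <- 1e-8
  lr <- spec$learning_rate
  M <- nrow(S)
  losses <- numeric(spec$epochs)
  step <- 0L
  eps <- 1e-7

  withr::with_seed(spec$seed + 1L, {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(M)
      ep_loss <- 0; ep_n <- 0L
      for (start in seq(1L, M, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1L, M)]
        A <- list(S[idx, , drop = FALSE])
        for (l in seq_len(L)) {
          Z <- sweep(A[[l]] %*% W[[l]], 2L, b[[l]], "+")
          A[[l + 1L]] <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
        }
        Y <- A[[L + 1L]]
        Tg <- A[[1L]]
        Yc <- pmin(pmax(Y, eps), 1 - eps)
        ep_loss <- ep_loss -
          sum(Tg * log(Yc) + (1 - Tg) * log(1 - Yc)) / ncol(S)
        ep_n <- ep_n + length(idx)
        # BCE + sigmoid output: delta = Y - T
        delta <- (Y - Tg) / (length(idx) * ncol(S))
        step <- step + 1L
        for (l in L:1L) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          cor1 <- 1 - beta1^step; cor2 <- 1 - beta2^step
          W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) /
            (sqrt(vW[[l]] / cor2) + epsb)
          b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) /
            (sqrt(vb[[l]] / cor2) + epsb)
        }
      }
      losses[ep] <- ep_loss / ep_n
    }
  })

  code_layer <- (length(spec$layer_widths) - 1L) %/% 2L  # transitions to code
  structure(list(W = W[seq_len(code_layer)], b = b[seq_len(code_layer)],
                 scale_min = lo, scale_range = rngv,
                 spec = spec, loss_history = losses),
            class = "ae_encoder")
}

#' Encode features with a trained encoder
#'
#' Applies the stored min-max scaling and the encoder layers; the code-layer
#' (ReLU) activations are the reduced features.
#'
#' @param encoder an `ae_encoder` from [train_autoencoder()].
#' @param X numeric matrix with the encoder's input width.
#' @return M x `code_dim` matrix.
#' @export
encode <- function(encoder, X) {
  stopifnot(inherits(encoder, "ae_encoder"))
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  A <- sweep(sweep(X, 2L, encoder$scale_min), 2L, encoder$scale_range, "/")
  for (l in seq_along(encoder$W))
    A <- pmax(sweep(A %*% encoder$W[[l]], 2L, encoder$b[[l]], "+"), 0)
  A
}
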