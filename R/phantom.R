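#' BI-RADS density bands
#'
#' Density categories are defined by the proportion of dense fibro-glandular
#' tissue within the breast area: I 0--25%, II 26--50%, III 51--75%,
#' IV >75%.
#'
#' @param class_label `"I"`, `"II"`, `"III"` or `"IV"`.
#' @return numeric length-2 vector, the (lower, upper] band (class I's lower
#'   bound is closed at 0).
#' @export
density_band <- function(class_label) {
  switch(match.arg(class_label, c("I", "II", "III", "IV")),
         I   = c(0.00, 0.25),
         II  = c(0.25, 0.50),
         III = c(0.50, 0.75),
         IV  = c(0.75, 1.00))
}

# Fraction of breast pixels above the fixed dense-intensity threshold.
DENSE_THRESHOLD <- 0.6

#' Phantom specification
#'
#' Parameters of one synthetic mammogram phantom. The phantom is a
#' half-elliptical bright breast region against a near-zero background,
#' with an added bright pectoral triangle in the upper chest-wall corner for
#' MLO views, a smooth fatty base texture, and Gaussian dense-tissue blobs
#' accumulated until the dense-pixel fraction lands inside the class band.
#'
#' @param class_label BI-RADS category `"I"`--`"IV"`.
#' @param image_size `(H, W)` in pixels, each >= 64.
#' @param view `"MLO"` (with pectoral triangle) or `"CC"`.
#' @param blob_count maximum number of blob additions before giving up.
#' @param blob_scale blob standard deviation in pixels; the default scales
#'   with image size (`min(H, W) / 32`) so a single blob adds only a small
#'   density increment at any resolution.
#' @param noise_sd additive Gaussian noise, in normalized intensity units.
#' @param seed integer RNG seed; the phantom is a pure function of the spec.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(class_label = "I", image_size = c(256L, 256L),
                         view = c("MLO", "CC"), blob_count = 600L,
                         blob_scale = NULL, noise_sd = 0.01, seed = 1L) {
  view <- match.arg(view)
  class_label <- match.arg(class_label, c("I", "II", "III", "IV"))
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 64L))
    stop("image_size must be (H, W) with both >= 64", call. = FALSE)
  if (is.null(blob_scale)) blob_scale <- max(2, round(min(image_size) / 32))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (blob_count < 1L) stop("blob_count must be positive", call. = FALSE)
  if (blob_scale <= 0) stop("blob_scale must be > 0", call. = FALSE)
  structure(list(class_label = class_label, image_size = image_size,
                 view = view, dense_fraction_band = density_band(class_label),
                 blob_count = as.integer(blob_count), blob_scale = blob_scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one synthetic mammogram phantom
#'
#' Deterministic per spec (identical spec + seed gives bitwise-identical
#' output). Geometry: a half-ellipse anchored on the left (chest-wall) edge;
#' MLO views add a bright pectoral triangle in the upper-left corner, which
#' is excluded from the breast mask. Dense tissue is built up by adding
#' Gaussian blobs inside the breast until the fraction of breast pixels
#' above the fixed dense threshold (0.6) reaches a target drawn inside the
#' class band; additive Gaussian noise is applied last. Blob centres keep a
#' margin from the pectoral edge so dense tissue and pectoral muscle stay
#' disconnected.
#'
#' @param spec a [phantom_spec()].
#' @return a `synthetic_sample` list: `image` (16-bit [gray_image()]),
#'   `breast_mask`, `pectoral_mask` (logical, disjoint), `label`,
#'   `realized_dense_fraction`, `seed`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_size[1L]; W <- spec$image_size[2L]
  withr::with_seed(spec$seed, {
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    a <- 0.80 * W      # horizontal semi-axis from the chest wall
    b <- 0.42 * H      # vertical semi-axis
    region <- ((cc - 1) / a)^2 + ((rr - H / 2) / b)^2 <= 1
    if (sum(region) < 500L)
      stop("image_size too small to place the breast region", call. = FALSE)

    if (spec$view == "MLO") {
      r0 <- 0.45 * H; c0 <- 0.38 * W
      tri <- (rr - 1) / r0 + (cc - 1) / c0 < 1
      pectoral <- tri & region
    } else {
      pectoral <- array(FALSE, c(H, W))
    }
    breast <- region & !pectoral

    img <- array(0.02, c(H, W))
    base <- 0.30 + 0.06 * generate_fbm_texture(0.5, c(H, W),
                                               seed = spec$seed + 1L)
    img[region] <- base[region]
    img[pectoral] <- 0.95

    band <- spec$dense_fraction_band
    target <- switch(spec$class_label,
                     I   = stats::runif(1, 0.06, 0.20),
                     II  = stats::runif(1, 0.30, 0.45),
                     III = stats::runif(1, 0.55, 0.70),
                     IV  = stats::runif(1, 0.80, 0.92))

    # keep blob cores clear of the pectoral edge so K-means components
    # stay separable downstream
    margin <- 2.5 * spec$blob_scale
    allowed <- breast
    if (spec$view == "MLO") {
      r0 <- 0.45 * H; c0 <- 0.38 * W
      allowed <- allowed &
        ((rr - 1) / r0 + (cc - 1) / c0 > 1 + margin / min(r0, c0))
    }
    centers <- which(allowed)
    if (length(centers) == 0L)
      stop("image_size too small to place the breast region", call. = FALSE)

    nb <- sum(breast)
    frac <- mean(img[breast] > DENSE_THRESHOLD)
    iter <- 0L
    while (frac < target && iter < spec$blob_count) {
      iter <- iter + 1L
      ci <- centers[sample.int(length(centers), 1L)]
      crow <- (ci - 1L) %% H + 1L
      ccol <- (ci - 1L) %/% H + 1L
      sig <- spec$blob_scale * stats::runif(1, 0.7, 1.3)
      amp <- 0.5 * stats::runif(1, 0.9, 1.1)
      ext <- ceiling(3.5 * sig)
      rs <- max(1L, crow - ext):min(H, crow + ext)
      cs <- max(1L, ccol - ext):min(W, ccol + ext)
      d2 <- outer((rs - crow)^2, (cs - ccol)^2, "+")
      patch <- img[rs, cs] + amp * exp(-d2 / (2 * sig^2))
      sel <- breast[rs, cs]
      patch[!sel] <- img[rs, cs][!sel]
      img[rs, cs] <- pmin(patch, 0.90)
      frac <- mean(img[breast] > DENSE_THRESHOLD)
    }
    if (frac < band[1L] || frac > band[2L])
      stop(sprintf(
        "could not reach the class %s density band (realized %.3f)",
        spec$class_label, frac), call. = FALSE)

    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
    img <- pmin(pmax(img, 0), 1)

    structure(list(
      image = gray_image(round(img * 65535), bit_depth = 16L,
                         view = spec$view),
      breast_mask = breast, pectoral_mask = pectoral,
      label = spec$class_label, realized_dense_fraction = frac,
      seed = spec$seed),
      class = "synthetic_sample")
  })
}

#' Fractional Brownian surface by spectral synthesis
#'
#' Complex Gaussian spectral coefficients with amplitude `f^-(H+1)` are
#' inverted by FFT and the real part min-max normalized to `[0, 1]`. Used as
#' the fatty-tissue base texture and as a calibration texture for alpha
#' estimation: smaller Hurst exponents give rougher surfaces.
#'
#' @param hurst Hurst exponent in `(0, 1)`.
#' @param size `(H, W)` in pixels.
#' @param seed integer RNG seed.
#' @return numeric matrix in `[0, 1]`.
#' @export
generate_fbm_texture <- function(hurst, size = c(128L, 128L), seed = 1L) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop("hurst must lie strictly between 0 and 1", call. = FALSE)
  H <- as.integer(size[1L]); W <- as.integer(size[2L])
  withr::with_seed(as.integer(seed), {
    fr <- c(0:(H %/% 2L), -((H - H %/% 2L - 1L):1L)) / H
    fc <- c(0:(W %/% 2L), -((W - W %/% 2L - 1L):1L)) / W
    f <- sqrt(outer(fr^2, fc^2, "+"))
    ampl <- ifelse(f == 0, 0, f^(-(hurst + 1)))
    phase <- matrix(stats::rnorm(H * W), H, W) +
             1i * matrix(stats::rnorm(H * W), H, W)
    surf <- Re(stats::fft(ampl * phase, inverse = TRUE)) / (H * W)
    rng <- range(surf)
    if (rng[1L] == rng[2L]) return(array(0, c(H, W)))
    (surf - rng[1L]) / (rng[2L] - rng[1L])
  })
}

#' Generate a labelled phantom dataset
#'
#' `4 * n_per_class` samples with per-sample seeds derived deterministically
#' from `base_seed`, plus a manifest data frame.
#'
#' @param n_per_class samples per BI-RADS class (>= 1).
#' @param base_seed integer; sample `j` of class `i` uses seed
#'   `base_seed + 1000*i + j`.
#' @param spec_defaults a [phantom_spec()] supplying everything except class
#'   and seed.
#' @return list with `samples` (list of `synthetic_sample`) and `manifest`
#'   (data frame: id, label, view, seed, dense_fraction).
#' @export
generate_dataset <- function(n_per_class, base_seed = 42L,
                             spec_defaults = phantom_spec()) {
  stopifnot(n_per_class >= 1L)
  classes <- c("I", "II", "III", "IV")
  samples <- list()
  rows <- list()
  k <- 0L
  for (i in seq_along(classes)) {
    for (j in seq_len(n_per_class)) {
      k <- k + 1L
      seed <- as.integer(base_seed + 1000L * i + j)
      sp <- spec_defaults
      sp$class_label <- classes[i]
      sp$dense_fraction_band <- density_band(classes[i])
      sp$seed <- seed
      samples[[k]] <- generate_phantom(sp)
      rows[[k]] <- data.frame(
        id = sprintf("phantom_%s_%03d", classes[i], j),
        label = classes[i], view = sp$view, seed = seed,
        dense_fraction = samples[[k]]$realized_dense_fraction,
        stringsAsFactors = FALSE)
    }
  }
  list(samples = samples, manifest = do.call(rbind, rows))
}

#' Write a phantom dataset to disk
#'
#' Images as 16-bit TIFF, masks as 8-bit PNG, and a CSV manifest with
#' columns file, mask, pectoral_mask, label, dense_fraction, seed.
#'
#' @param ds result of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest data frame (with file columns), invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- ds$manifest
  man$file <- file.path(dir, paste0(man$id, ".tif"))
  man$mask <- file.path(dir, paste0(man$id, "_breast.png"))
  man$pectoral_mask <- file.path(dir, paste0(man$id, "_pectoral.png"))
  for (i in seq_along(ds$samples)) {
    s <- ds$samples[[i]]
    write_image(s$image, man$file[i])
    write_mask(s$breast_mask, man$mask[i])
    write_mask(s$pectoral_mask, man$pectoral_mask[i])
  }
  utils::write.csv(man[, c("file", "mask", "pectoral_mask", "label",
                           "dense_fraction", "seed")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
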