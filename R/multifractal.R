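#' Multi-fractal analysis configuration
#'
#' Settings for local-measure evaluation and Hoelder-exponent (alpha)
#' estimation. The local measure `mu_w(p)` is evaluated over square windows
#' of odd width `w` centred at each pixel `p`, and alpha is the slope of
#' `log mu_w(p)` against `log w`.
#'
#' @param measure one of `"maximum"`, `"inverse_minimum"`, `"summation"`,
#'   `"iso"`.
#' @param window_sizes strictly increasing odd window widths (>= 2 values
#'   required for the regression). Default `c(1, 3, 5)`.
#' @param iso_tolerance tolerance `tau` for the iso measure's near-equality
#'   test, in normalized intensity units. The default `1/255` reproduces
#'   integer equality on 8-bit data.
#' @param log_floor positive floor applied to measures before taking logs
#'   (the inverse-minimum measure can reach 0 exactly).
#' @param n_bins number of alpha-histogram bins.
#' @return a `mf_config` list.
#' @export
mf_config <- function(measure = c("maximum", "inverse_minimum",
                                  "summation", "iso"),
                      window_sizes = c(1L, 3L, 5L),
                      iso_tolerance = 1 / 255,
                      log_floor = 1e-12,
                      n_bins = 100L) {
  measure <- match.arg(measure)
  w <- as.integer(window_sizes)
  if (length(w) < 2L) stop("need >= 2 window sizes for the regression",
                           call. = FALSE)
  if (any(w < 1L) || any(w %% 2L == 0L))
    stop("window sizes must be odd and >= 1", call. = FALSE)
  if (is.unsorted(w, strictly = TRUE))
    stop("window sizes must be strictly increasing", call. = FALSE)
  if (iso_tolerance < 0) stop("iso_tolerance must be >= 0", call. = FALSE)
  if (log_floor <= 0) stop("log_floor must be > 0", call. = FALSE)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  structure(list(measure = measure, window_sizes = w,
                 iso_tolerance = iso_tolerance, log_floor = log_floor,
                 n_bins = as.integer(n_bins)),
            class = "mf_config")
}

#' Evaluate a local multi-fractal measure map
#'
#' For every pixel `p` the measure is computed over the `w x w`
#' reflect-padded window centred at `p`:
#' maximum `max g`, inverse-minimum `1 - min g`, summation `sum g`, and iso
#' `#\{(k,l) : |g(k,l) - g(p)| <= tau\}` (centre pixel included). With
#' `w = 1` the window is the pixel itself.
#'
#' @param img normalized image (matrix in `[0,1]`).
#' @param w odd window width.
#' @param cfg an [mf_config()].
#' @return numeric matrix of measure values.
#' @export
compute_measure_map <- function(img, w, cfg) {
  x <- as_pixels(img)
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L)
    stop("window size must be odd and >= 1", call. = FALSE)
  r <- (w - 1L) %/% 2L
  if (r == 0L) {
    return(switch(cfg$measure,
      maximum = x,
      inverse_minimum = 1 - x,
      summation = x,
      iso = array(1, dim(x))))
  }
  p <- pad_reflect(x, r)
  H <- nrow(x); W <- ncol(x)
  acc <- NULL
  for (dr in -r:r) for (dc in -r:r) {
    s <- p[(1L:H) + r + dr, (1L:W) + r + dc, drop = FALSE]
    acc <- switch(cfg$measure,
      maximum = if (is.null(acc)) s else pmax(acc, s),
      inverse_minimum = if (is.null(acc)) s else pmin(acc, s),
      summation = if (is.null(acc)) s else acc + s,
      iso = {
        hit <- (abs(s - x) <= cfg$iso_tolerance) * 1
        if (is.null(acc)) hit else acc + hit
      })
  }
  if (cfg$measure == "inverse_minimum") acc <- 1 - acc
  acc
}

#' Estimate per-pixel Hoelder exponents from a measure stack
#'
#' Ordinary least-squares fit of `log mu_w` against `log w` at every pixel;
#' the slope is the alpha map, the intercept `log C`. Measures are floored
#' at `log_floor` before the logarithm.
#'
#' @param stack named list of measure maps, one per window size.
#' @param window_sizes the window widths, matching `stack` order.
#' @param log_floor positive floor for the logarithm.
#' @return an `alpha_img` list with `alpha` and `intercept` matrices.
#' @export
estimate_alpha <- function(stack, window_sizes, log_floor = 1e-12) {
  if (length(stack) < 2L || length(stack) != length(window_sizes))
    stop("need >= 2 measure maps matching window_sizes", call. = FALSE)
  lw <- log(as.numeric(window_sizes))
  lwc <- lw - mean(lw)
  denom <- sum(lwc^2)
  ybar <- 0; slope <- 0
  for (i in seq_along(stack)) {
    y <- log(pmax(stack[[i]], log_floor))
    slope <- slope + lwc[i] * y
    ybar <- ybar + y
  }
  slope <- slope / denom
  ybar <- ybar / length(stack)
  structure(list(alpha = slope, intercept = ybar - slope * mean(lw),
                 window_sizes = as.numeric(window_sizes)),
            class = "alpha_img")
}

#' Compute the alpha-image of a mammogram
#'
#' Normalizes the image, evaluates the configured measure at every window
#' size and regresses `log mu_w` on `log w` per pixel. The alpha-image is
#' computed over the full grid; ROI restriction happens at histogram time.
#'
#' @param img [gray_image()] or numeric matrix.
#' @param cfg an [mf_config()].
#' @param normalize min-max normalize first (set `FALSE` when the input is
#'   already on the intended `[0,1]` scale).
#' @return an `alpha_img` (see [estimate_alpha()]) with the measure recorded.
#' @export
alpha_image <- function(img, cfg, normalize = TRUE) {
  x <- if (normalize) normalize_intensity(img) else as_pixels(img)
  stack <- lapply(cfg$window_sizes, function(w) compute_measure_map(x, w, cfg))
  ai <- estimate_alpha(stack, cfg$window_sizes, cfg$log_floor)
  ai$measure <- cfg$measure
  ai
}

#' ROI-restricted alpha-histogram
#'
#' The alpha range over ROI pixels is divided into `n_bins` equal-width bins
#' (last bin right-closed) and bin heights are the *proportion* of ROI
#' pixels falling in each bin, making histograms comparable between breasts
#' of different areas. A degenerate range (constant alpha) puts all mass in
#' the first bin.
#'
#' @param ai an `alpha_img` from [alpha_image()], or a bare alpha matrix.
#' @param mask logical ROI mask of the same shape.
#' @param n_bins number of bins (default 100).
#' @return an `alpha_histogram` list: `heights` (sums to 1), `range`,
#'   `roi_pixel_count`.
#' @export
alpha_histogram <- function(ai, mask, n_bins = 100L) {
  amap <- if (inherits(ai, "alpha_img")) ai$alpha else ai
  stopifnot(is.matrix(amap), all(dim(mask) == dim(amap)))
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  v <- amap[mask]
  n_bins <- as.integer(n_bins)
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    heights <- c(1, rep(0, n_bins - 1L))
  } else {
    bin <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1L) + 1L
    heights <- tabulate(bin, nbins = n_bins) / length(v)
  }
  structure(list(heights = heights, range = c(lo, hi),
                 roi_pixel_count = length(v)),
            class = "alpha_histogram")
}

#' Alpha-histogram feature vector for one image
#'
#' Convenience wrapper: [alpha_image()] then [alpha_histogram()], returning
#' the named 100-bin feature block used by the fused descriptor.
#'
#' @inheritParams alpha_image
#' @param mask logical ROI mask.
#' @return named numeric vector `a_000 ... a_<n-1>`.
#' @export
mf_descriptor <- function(img, mask, cfg = mf_config("iso"),
                          normalize = TRUE) {
  h <- alpha_histogram(alpha_image(img, cfg, normalize), mask, cfg$n_bins)
  stats::setNames(h$heights,
                  sprintf("a_%03d", seq_len(cfg$n_bins) - 1L))
}
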