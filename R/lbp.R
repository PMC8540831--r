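#' @name lbp
#' @title Local binary pattern code maps and histograms
#'
#' @description
#' A pixel's LBP code compares its grey level `g_c` with `P` neighbours
#' sampled on a circle of radius `R` (or an ellipse with semi-axes
#' `R1`, `R2`): bit `i` is 1 when `g_i - g_c >= 0` and is weighted `2^i`.
#' Neighbours start due east and proceed counter-clockwise at angles
#' `2*pi*i/P`, sampled by bilinear interpolation with reflected borders.
#' Codes therefore depend only on the *ordering* of intensities, which makes
#' the descriptors invariant to monotone intensity transforms.
NULL

# Bilinear sample of x at (row + dr, col + dc) for every pixel, with
# symmetric border reflection. Offsets within 1e-9 of an integer are snapped
# so axis-aligned neighbours are read exactly.
bilinear_shift <- function(x, dr, dc) {
  if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
  if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
  H <- nrow(x); W <- ncol(x)
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0; fc <- dc - c0
  rows0 <- reflect_index(seq_len(H) + r0, H)
  cols0 <- reflect_index(seq_len(W) + c0, W)
  if (fr == 0 && fc == 0) return(x[rows0, cols0, drop = FALSE])
  rows1 <- reflect_index(seq_len(H) + r0 + 1L, H)
  cols1 <- reflect_index(seq_len(W) + c0 + 1L, W)
  (1 - fr) * (1 - fc) * x[rows0, cols0, drop = FALSE] +
  (1 - fr) * fc       * x[rows0, cols1, drop = FALSE] +
  fr       * (1 - fc) * x[rows1, cols0, drop = FALSE] +
  fr       * fc       * x[rows1, cols1, drop = FALSE]
}

# Shared engine for circular and elliptical neighbourhoods. r_row is the
# vertical semi-axis, r_col the horizontal one.
.code_map <- function(x, P, r_row, r_col) {
  if (P < 4L) stop("P must be >= 4", call. = FALSE)
  if (r_row <= 0 || r_col <= 0) stop("radii must be > 0", call. = FALSE)
  codes <- array(0, dim(x))
  for (i in seq_len(P) - 1L) {
    theta <- 2 * pi * i / P
    gi <- bilinear_shift(x, dr = -r_row * sin(theta), dc = r_col * cos(theta))
    # tolerance keeps interpolation round-off from flipping exact ties
    # (s(0) = 1); 1e-12 is far below any intensity quantization step
    codes <- codes + (gi - x >= -1e-12) * 2^i
  }
  codes
}

#' Circular LBP code map
#' @param img normalized image matrix or [gray_image()].
#' @param P number of neighbours (>= 4).
#' @param R circle radius in pixels.
#' @return integer-valued matrix of codes in `[0, 2^P - 1]`.
#' @export
lbp_code_map <- function(img, P = 8L, R = 1) {
  .code_map(as_pixels(img), as.integer(P), R, R)
}

#' Elliptical LBP code map
#'
#' Neighbours lie on an ellipse with semi-minor axis `R1` (vertical) and
#' semi-major axis `R2` along image rows; `R1 = R2` degenerates to
#' [lbp_code_map()].
#'
#' @inheritParams lbp_code_map
#' @param R1 semi-minor axis (pixels).
#' @param R2 semi-major axis (pixels).
#' @export
elbp_code_map <- function(img, P = 8L, R1 = 1, R2 = 4) {
  .code_map(as_pixels(img), as.integer(P), R1, R2)
}

#' ROI-normalized code histogram
#'
#' Counts codes over ROI pixels only and divides by the ROI pixel count, so
#' the `2^P` bin heights sum to 1 regardless of breast area.
#'
#' @param codes code map from [lbp_code_map()] / [elbp_code_map()].
#' @param mask logical ROI mask.
#' @param P number of neighbours used to build the map.
#' @return numeric vector of length `2^P` summing to 1.
#' @export
code_histogram <- function(codes, mask, P = 8L) {
  stopifnot(all(dim(codes) == dim(mask)))
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  v <- codes[mask]
  tabulate(v + 1L, nbins = 2L^as.integer(P)) / length(v)
}

#' Multi-resolution LBP descriptor
#'
#' One code histogram per radius (each normalized to sum 1), concatenated in
#' increasing-radius order. The default radii `{2, 4}` with `P = 8` give the
#' 512-length descriptor used for fusion with the alpha-histogram.
#'
#' @inheritParams lbp_code_map
#' @param mask logical ROI mask.
#' @param radii strictly increasing circle radii.
#' @return named numeric vector of length `length(radii) * 2^P`.
#' @export
mlbp_descriptor <- function(img, mask, radii = c(2, 4), P = 8L) {
  if (is.unsorted(radii, strictly = TRUE))
    stop("radii must be strictly increasing", call. = FALSE)
  x <- as_pixels(img)
  out <- unlist(lapply(radii, function(R)
    code_histogram(lbp_code_map(x, P, R), mask, P)))
  names(out) <- sprintf("mlbp_%03d", seq_along(out) - 1L)
  out
}

#' Single-radius LBP descriptor (256 bins at `P = 8`, `R = 2`)
#' @inheritParams mlbp_descriptor
#' @param R circle radius.
#' @return named numeric vector of length `2^P`.
#' @export
lbp_descriptor <- function(img, mask, R = 2, P = 8L) {
  h <- code_histogram(lbp_code_map(img, P, R), mask, P)
  stats::setNames(h, sprintf("lbp_%03d", seq_along(h) - 1L))
}

#' Elliptical LBP descriptor (256 bins at `P = 8`, semi-axes 1 and 4)
#' @inheritParams mlbp_descriptor
#' @param R1,R2 semi-minor and semi-major axes.
#' @return named numeric vector of length `2^P`.
#' @export
elbp_descriptor <- function(img, mask, R1 = 1, R2 = 4, P = 8L) {
  h <- code_histogram(elbp_code_map(img, P, R1, R2), mask, P)
  stats::setNames(h, sprintf("elbp_%03d", seq_along(h) - 1L))
}
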