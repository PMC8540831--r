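#' Segment the breast region from a normalized mammogram
#'
#' Otsu thresholding followed by morphological opening, hole filling and
#' retention of the largest 4-connected component. When Otsu on the raw
#' intensities yields no foreground (flat, very low-contrast images), the
#' inverse-minimum alpha-image is thresholded instead: that measure amplifies
#' the background/tissue transition and rescues the threshold.
#'
#' @param img normalized image (matrix in `[0,1]` or [gray_image()], which is
#'   normalized internally).
#' @param opening_radius structuring-element radius in pixels; default scales
#'   a 5-px disc at 512-px image width proportionally.
#' @return logical breast mask (background excluded, pectoral still included
#'   for MLO views; see [remove_pectoral()]).
#' @export
segment_breast <- function(img, opening_radius = NULL) {
  x <- as_pixels(img)
  if (nrow(x) < 64L || ncol(x) < 64L)
    stop("image too small to segment (need >= 64x64)", call. = FALSE)
  if (max(x) > 1) x <- normalize_intensity(x)
  if (is.null(opening_radius))
    opening_radius <- max(1L, round(5 * ncol(x) / 512))

  bin <- .threshold_foreground(x)
  if (is.null(bin)) {
    # contrast-enhancement fallback: alpha-image of the inverse-minimum measure
    cfg <- mf_config("inverse_minimum")
    ai <- alpha_image(x, cfg, normalize = FALSE)
    amap <- normalize_intensity(ai$alpha)
    bin <- .threshold_foreground(amap)
    if (is.null(bin))
      stop("segmentation failure: no foreground component found",
           call. = FALSE)
  }

  side <- 2L * opening_radius + 1L
  brush <- EBImage::makeBrush(side, shape = "disc")
  opened <- EBImage::opening(bin, brush)
  filled <- EBImage::fillHull(opened)
  lab <- EBImage::bwlabel(filled)          # 4-connected labelling
  n <- max(lab)
  if (n < 1L)
    stop("segmentation failure: no foreground component found", call. = FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which.max(sizes)
  m <- lab == keep
  dim(m) <- dim(x)
  m
}

# Otsu threshold with a tri-level refinement; NULL when nothing (or
# everything) survives. On dense breasts the intensity histogram has three
# modes (background, fatty tissue, dense tissue) and a single Otsu cut can
# land between fatty and dense; when the sub-threshold population itself
# splits into two classes whose means are far apart (> 0.1 in normalized
# units), that lower cut is the true background/tissue boundary.
.threshold_foreground <- function(x) {
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  sub <- x[x <= th]
  if (length(sub) > 1L && min(sub) < max(sub)) {
    th0 <- EBImage::otsu(EBImage::Image(matrix(sub)), range = c(0, 1))
    lo <- sub[sub <= th0]; hi <- sub[sub > th0]
    if (length(lo) && length(hi) && mean(hi) - mean(lo) > 0.1) th <- th0
  }
  bin <- x > th
  n <- sum(bin)
  if (n == 0L || n == length(bin)) NULL else bin
}

#' Remove the pectoral muscle from an MLO breast mask
#'
#' The pectoral muscle appears as a bright triangular region in the
#' chest-wall upper corner of MLO views and would otherwise inflate density
#' estimates. Intensities inside the mask are split by 2-cluster K-means
#' (deterministic quantile-seeded centers); the bright cluster's 4-connected
#' component touching the upper-left corner is taken as pectoral, its per-row
#' outer boundary smoothed by a degree-2 polynomial, and everything on the
#' chest-wall side of the fitted curve is dropped from the mask. CC views are
#' returned unchanged. The image must be oriented chest-wall-left (see
#' [orient_chest_left()]).
#'
#' @param img normalized image matrix or [gray_image()].
#' @param mask logical mask from [segment_breast()].
#' @param view `"MLO"` or `"CC"`.
#' @param poly_degree degree of the boundary-smoothing polynomial.
#' @return logical mask, a subset of `mask`.
#' @export
remove_pectoral <- function(img, mask, view = c("MLO", "CC"),
                            poly_degree = 2L) {
  view <- match.arg(view)
  x <- as_pixels(img)
  stopifnot(is.matrix(mask), all(dim(mask) == dim(x)))
  if (!any(mask)) stop("empty input mask", call. = FALSE)
  if (view == "CC") return(mask)
  if (max(x) > 1) x <- normalize_intensity(x)

  v <- x[mask]
  ctr <- stats::quantile(v, c(0.25, 0.95), names = FALSE)
  if (ctr[1L] >= ctr[2L]) return(mask)  # flat intensities: nothing to split
  km <- stats::kmeans(v, centers = matrix(ctr, ncol = 1L))
  bright <- which.max(km$centers)
  bmap <- array(FALSE, dim(x))
  bmap[mask] <- km$cluster == bright

  lab <- EBImage::bwlabel(bmap)
  n <- max(lab)
  if (n < 1L) return(mask)
  H <- nrow(x); W <- ncol(x)
  corner_r <- max(2L, round(0.12 * H)); corner_c <- max(2L, round(0.12 * W))
  corner_lab <- lab[seq_len(corner_r), seq_len(corner_c)]
  cand <- setdiff(unique(as.vector(corner_lab)), 0L)
  if (length(cand) == 0L) return(mask)  # no bright region at the corner
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  pect <- lab == cand[which.max(sizes[cand])]
  dim(pect) <- dim(x)

  idx <- which(pect, arr.ind = TRUE)
  rows <- sort(unique(idx[, 1L]))
  edge <- vapply(rows, function(r) max(idx[idx[, 1L] == r, 2L]), numeric(1))
  out <- mask
  if (length(rows) <= poly_degree + 1L) {
    out[pect] <- FALSE
    return(out)
  }
  fit <- stats::lm(edge ~ stats::poly(rows, degree = poly_degree, raw = TRUE))
  cut <- stats::predict(fit, data.frame(rows = rows)) + 2  # small safety margin
  colgrid <- matrix(seq_len(W), H, W, byrow = TRUE)
  cutcol <- rep(-Inf, H)
  cutcol[rows] <- cut
  out[colgrid <= matrix(cutcol, H, W)] <- FALSE
  out
}

#' Dice overlap coefficient between two binary masks
#' @param a,b logical matrices of equal shape.
#' @return `2|A∩B| / (|A|+|B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}
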