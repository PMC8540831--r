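#' Grayscale image container
#'
#' Thin S3 wrapper around a numeric intensity matrix. Intensities are raw
#' detector counts (non-negative integers up to `2^bit_depth - 1`); use
#' [normalize_intensity()] to map them to the unit range expected by the
#' texture operators.
#'
#' @param pixels numeric matrix of non-negative, finite intensities
#'   (rows = image rows, columns = image columns).
#' @param bit_depth integer bit depth of the encoding (8--16 typical;
#'   full-field digital mammography uses 14-bit contrast resolution).
#' @param view mammographic projection: `"MLO"`, `"CC"` or `"unknown"`.
#' @param laterality `"L"`, `"R"` or `"unknown"`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, bit_depth = 16L,
                       view = c("unknown", "MLO", "CC"),
                       laterality = c("unknown", "L", "R")) {
  view <- match.arg(view)
  laterality <- match.arg(laterality)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         view = view, laterality = laterality),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d-bit, view=%s, laterality=%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$view,
              x$laterality))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

# Accept either a gray_image or a bare matrix anywhere a pixel grid is needed.
as_pixels <- function(img) {
  if (inherits(img, "gray_image")) img$pixels
  else if (is.matrix(img) && is.numeric(img)) img
  else stop("expected a `gray_image` or a numeric matrix", call. = FALSE)
}

#' Read a grayscale image from disk
#'
#' Supports lossless PNG and TIFF. Intensities are returned as integer counts
#' at the file's native bit depth; a color (multi-channel) file is rejected.
#' DICOM is not supported by this build and raises a format error.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @param view,laterality optional tags to attach (PNG/TIFF carry none).
#' @return A [gray_image()].
#' @export
read_image <- function(path, view = "unknown", laterality = "unknown") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom"))
    stop("DICOM input is not supported; convert to 16-bit PNG/TIFF first",
         call. = FALSE)
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    depth <- as.integer(info$bit.depth)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    depth <- as.integer(attr(arr, "bits.per.sample"))
    if (length(depth) != 1L || is.na(depth)) depth <- 16L
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] > 1L)
      stop("color image: grayscale input required", call. = FALSE)
    arr <- arr[, , 1L]
  }
  # readers return [0,1]; undo the scaling to recover exact integer counts
  px <- round(unclass(arr) * (2^depth - 1))
  attributes(px) <- list(dim = dim(arr))
  gray_image(px, bit_depth = depth, view = view, laterality = laterality)
}

#' Write a grayscale image to disk
#'
#' PNG output is 8-bit; TIFF output preserves 16-bit depth. Intensities are
#' taken as counts at `img$bit_depth` and rescaled to the target encoding.
#'
#' @param img a [gray_image()] or numeric matrix of counts.
#' @param path destination ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- as_pixels(img)
  depth <- if (inherits(img, "gray_image")) img$bit_depth else 16L
  unit <- px / (2^depth - 1)
  unit <- pmin(pmax(unit, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(unit, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(unit, path, bits.per.sample = 16L)
  } else stop("unsupported output format: .", ext, call. = FALSE)
  invisible(path)
}

#' Write a binary ROI mask as an 8-bit PNG (0/255)
#' @param mask logical matrix.
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path `.png` path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  unclass(arr) > 0.5
}

#' Normalize intensities to the unit range
#'
#' Min-max normalization over the full image: `(x - min) / (max - min)`.
#' A constant image maps to all zeros. The non-linear amplification of the
#' logarithm used in Hoelder-exponent estimation makes this normalization
#' load-bearing for the maximum and inverse-minimum measures.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @return numeric matrix with values in `[0, 1]`.
#' @export
normalize_intensity <- function(img) {
  x <- as_pixels(img)
  if (any(!is.finite(x))) stop("non-finite intensities", call. = FALSE)
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(array(0, dim(x)))
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

# Symmetric (edge-repeating) reflection of 1-based indices into 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Pad a matrix by r pixels on every side with symmetric reflection.
pad_reflect <- function(x, r) {
  if (r == 0L) return(x)
  ri <- reflect_index(seq(1L - r, nrow(x) + r), nrow(x))
  ci <- reflect_index(seq(1L - r, ncol(x) + r), ncol(x))
  x[ri, ci, drop = FALSE]
}

#' 3x3 median filter
#'
#' Replaces each pixel by the median of its 3x3 neighborhood with reflected
#' borders. Implemented as a vectorized median-of-9 selection network so it
#' stays fast on full-size images.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @return numeric matrix of the same shape.
#' @export
median_filter3 <- function(img) {
  x <- as_pixels(img)
  p <- pad_reflect(x, 1L)
  H <- nrow(x); W <- ncol(x)
  v <- vector("list", 9L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    v[[k]] <- p[(1L:H) + 1L + dr, (1L:W) + 1L + dc, drop = FALSE]
  }
  sw <- function(a, b) { lo <- pmin(v[[a]], v[[b]]); hi <- pmax(v[[a]], v[[b]])
                         v[[a]] <<- lo; v[[b]] <<- hi }
  # Devillard's 19-exchange median-of-9 network
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  v[[5]]
}

#' Orient an image chest-wall-left
#'
#' Pectoral removal assumes the chest wall lies along the left image edge.
#' Right-lateral images (or images whose breast mass sits on the right,
#' judged by column sums when laterality is unknown) are mirrored.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param laterality `"L"`, `"R"` or `"unknown"`.
#' @return list with `pixels` (possibly mirrored matrix) and `flipped` flag.
#' @export
orient_chest_left <- function(img, laterality = "unknown") {
  x <- as_pixels(img)
  if (inherits(img, "gray_image") && laterality == "unknown")
    laterality <- img$laterality
  flip <- if (laterality == "R") TRUE
          else if (laterality == "L") FALSE
          else {
            half <- ncol(x) %/% 2L
            sum(x[, seq_len(half)]) < sum(x[, ncol(x) - seq_len(half) + 1L])
          }
  if (flip) x <- x[, ncol(x):1L, drop = FALSE]
  list(pixels = x, flipped = flip)
}
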