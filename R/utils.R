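# Shared numeric helpers. Images are base-R arrays: a slide raster is
# array(dim = c(rows, cols, 3)) with channel values in [0, 1], origin at the
# top-left corner, x = column index, y = row index.

#' Clip values into the unit interval
#'
#' @param x numeric vector, matrix or array.
#' @return `x` with every element clamped to `[0, 1]`.
#' @export
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Relative luminance of an RGB raster
#'
#' Rec. 709 luminance `0.2126 R + 0.7152 G + 0.0722 B`, the scalar brightness
#' used throughout for overlay readouts.
#'
#' @param pixels array `c(rows, cols, 3)` in `[0, 1]`, or a `slide_image`.
#' @return matrix of luminance values.
#' @export
luminance <- function(pixels) {
  if (inherits(pixels, "slide_image")) pixels <- pixels$pixels
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  0.2126 * pixels[, , 1] + 0.7152 * pixels[, , 2] + 0.0722 * pixels[, , 3]
}

#' Quantize a raster to a fixed bit depth
#'
#' Rounds channel values to the levels an integer scanner image would hold,
#' so that in-memory rasters and their lossless file round-trips agree
#' bit-for-bit.
#'
#' @param x numeric array in `[0, 1]`.
#' @param bit_depth integer bits per sample, or `NULL` to leave `x` untouched.
#' @return quantized array.
#' @export
quantize <- function(x, bit_depth = 16L) {
  if (is.null(bit_depth)) return(x)
  levels <- 2^bit_depth - 1
  round(x * levels) / levels
}

#' Mean of a raster over a disc
#'
#' @param values numeric matrix.
#' @param x_px,y_px disc center in pixel units (x = column, y = row; pixel
#'   centers at integer coordinates).
#' @param r_px disc radius in pixels.
#' @param trim fraction trimmed from each tail of the pixel distribution
#'   before averaging; a modest trim makes soma-disc means robust to stray
#'   punctum pixels inside the disc while preserving linear scaling.
#' @return mean of the in-raster pixels whose centers fall inside the disc.
#'   Errors if the disc lies entirely outside the raster.
#' @export
disc_mean <- function(values, x_px, y_px, r_px, trim = 0) {
  nr <- nrow(values); nc <- ncol(values)
  i0 <- max(1L, floor(y_px - r_px)); i1 <- min(nr, ceiling(y_px + r_px))
  j0 <- max(1L, floor(x_px - r_px)); j1 <- min(nc, ceiling(x_px + r_px))
  if (i0 > i1 || j0 > j1) stop("disc lies entirely outside the raster")
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer((ii - y_px)^2, (jj - x_px)^2, `+`)
  sel <- d2 <= r_px^2
  if (!any(sel)) stop("disc lies entirely outside the raster")
  mean(values[ii, jj][sel], trim = trim)
}

# Robust background statistics of a (mostly background) map.
robust_bg <- function(values) {
  v <- as.numeric(values)
  m <- stats::median(v)
  list(median = m, mad = stats::mad(v, center = m))
}

# Isotropic Gaussian blur of a plain matrix (EBImage's FFT implementation;
# isotropic, so the row/column convention is immaterial). Replicated edges,
# not circular: opposite field borders are unrelated tissue.
gauss_smooth <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma_px, boundary = "replicate"))
}

# Deterministic per-purpose sub-seed so independent stages draw from
# independent streams of one top-level seed.
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.numeric(seed) * 48271 + h * 9973) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
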