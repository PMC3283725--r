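#' Scalar marker signal map
#'
#' A per-pixel, bright-on-dark marker signal in `[0, 1]`, derived from a
#' brightfield scan. `frame` records whether the map is still in its own
#' round's native frame or has been warped into the series reference frame.
#'
#' @param values numeric matrix in `[0, 1]`.
#' @param marker marker name.
#' @param pixel_size_um micron per pixel.
#' @param frame `"native"` or `"reference"`.
#' @return object of class `signal_map`.
#' @export
signal_map <- function(values, marker, pixel_size_um = 0.5,
                       frame = c("native", "reference")) {
  stopifnot(is.matrix(values), min(values) >= 0, max(values) <= 1)
  structure(list(values = values, marker = marker,
                 pixel_size_um = pixel_size_um,
                 frame = match.arg(frame)),
            class = "signal_map")
}

#' @export
print.signal_map <- function(x, ...) {
  cat(sprintf("signal_map: %s, %d x %d px at %g um/px (%s frame)\n",
              x$marker, ncol(x$values), nrow(x$values), x$pixel_size_um,
              x$frame))
  invisible(x)
}

#' @export
dim.signal_map <- function(x) dim(x$values)

#' Blank-slide white balance
#'
#' Divides each channel by the blank reference's per-channel median (robust
#' to blank noise) and clips to `[0, 1]`, removing the scanner's illumination
#' color and gain. Without a blank reference the image passes through with a
#' warning.
#'
#' @param image [slide_image()] whose `blank_reference` matches its
#'   dimensions.
#' @return white-balanced `slide_image` (blank reference replaced by its
#'   normalized self).
#' @export
white_balance <- function(image) {
  stopifnot(inherits(image, "slide_image"))
  blank <- image$blank_reference
  if (is.null(blank)) {
    warning("no blank reference; image passed through un-balanced")
    return(image)
  }
  if (!identical(dim(blank), dim(image$pixels)))
    stop("blank reference dimensions do not match the image")
  med <- apply(blank, 3, stats::median)
  if (any(med <= 0)) stop("blank reference has a zero-median channel")
  for (ch in 1:3) {
    image$pixels[, , ch] <- image$pixels[, , ch] / med[ch]
    image$blank_reference[, , ch] <- blank[, , ch] / med[ch]
  }
  image$pixels <- clip01(image$pixels)
  image$blank_reference <- clip01(image$blank_reference)
  image
}

#' Per-channel color inversion
#'
#' Replaces every channel value `c` by `1 - c`, turning dark stain on a white
#' background into bright signal on a dark background. An involution:
#' inverting twice restores the image exactly.
#'
#' @param image [slide_image()] or an RGB array.
#' @return inverted object of the same kind.
#' @export
invert_image <- function(image) {
  if (inherits(image, "slide_image")) {
    image$pixels <- 1 - image$pixels
    return(image)
  }
  1 - image
}

#' Extract a scalar signal map from a white-balanced scan
#'
#' Default mode `"inverted_luminance"`: one minus the Rec. 709 relative
#' luminance, the scalar counterpart of plain color inversion. Mode
#' `"deconvolution"`: the per-pixel optical-density vector (`-log` of each
#' channel, floored at `od_floor` transmittance) projected onto the unit
#' chromogen OD direction, rescaled so its 99.9th percentile maps to 1
#' (robust to hot pixels) and clipped to `[0, 1]`. Deconvolution is linear in
#' stain absorbance and therefore preferred for quantification of unsaturated
#' staining; inverted luminance is the faithful analog of the visual
#' inversion operation.
#'
#' @param image white-balanced [slide_image()].
#' @param mode `"inverted_luminance"` or `"deconvolution"`.
#' @param chromogen_od chromogen OD direction used by deconvolution.
#' @param od_floor transmittance floor guarding the logarithm.
#' @return [signal_map()] in the image's native frame.
#' @export
extract_signal <- function(image,
                           mode = c("inverted_luminance", "deconvolution"),
                           chromogen_od = c(0.30, 0.70, 0.65),
                           od_floor = 1e-4) {
  stopifnot(inherits(image, "slide_image"))
  mode <- match.arg(mode)
  px <- image$pixels
  if (!all(is.finite(px))) stop("image contains non-finite pixels")
  if (mode == "inverted_luminance") {
    v <- 1 - luminance(px)
  } else {
    u <- chromogen_od / sqrt(sum(chromogen_od^2))
    od <- array(-log(pmax(px, od_floor)), dim(px))
    v <- od[, , 1] * u[1] + od[, , 2] * u[2] + od[, , 3] * u[3]
    hi <- stats::quantile(v, 0.999, names = FALSE)
    if (hi > 0) v <- v / hi
  }
  signal_map(clip01(v), image$marker, image$pixel_size_um, "native")
}
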