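#' Multiplicative superimposition of an inverted round onto another round
#'
#' The per-channel product of the two rasters. With the first argument an
#' inverted (bright-on-dark) round and the second an untouched (dark-on-white)
#' round, cells positive only in the first round stay bright over the white
#' base, co-localized cells are dimmed into the dark background by the
#' underlying stain, and unstained background stays dark. Multiplication is
#' the unique standard blend with all three behaviors: a screen or additive
#' blend would not dim co-localized cells.
#'
#' @param inverted,base [slide_image()] objects or RGB arrays of equal
#'   dimensions, both in the reference frame.
#' @return object of class `overlay_image` (fields `pixels`, `scheme`,
#'   `markers`).
#' @export
superimpose_multiply <- function(inverted, base) {
  a <- if (inherits(inverted, "slide_image")) inverted$pixels else inverted
  b <- if (inherits(base, "slide_image")) base$pixels else base
  if (!identical(dim(a), dim(b)))
    stop("overlay inputs must share dimensions")
  markers <- c(if (inherits(inverted, "slide_image")) inverted$marker,
               if (inherits(base, "slide_image")) base$marker)
  overlay_image(a * b, "invert_A_over_B", markers)
}

overlay_image <- function(pixels, scheme, markers = NULL, colors = NULL) {
  structure(list(pixels = clip01(pixels), scheme = scheme,
                 markers = markers, colors = colors),
            class = "overlay_image")
}

#' @export
print.overlay_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("overlay_image: scheme %s, %d x %d px%s\n", x$scheme, d[2], d[1],
              if (is.null(x$markers)) ""
              else paste0(" (", paste(x$markers, collapse = ", "), ")")))
  invisible(x)
}

#' Pseudocolor a signal map
#'
#' Maps the scalar signal to a display hue: each pixel becomes
#' `signal * display_color`.
#'
#' @param signal [signal_map()] or matrix in `[0, 1]`.
#' @param display_color length-3 RGB triple in `[0, 1]`.
#' @return RGB array `c(rows, cols, 3)`.
#' @export
recolor <- function(signal, display_color) {
  v <- if (inherits(signal, "signal_map")) signal$values else signal
  stopifnot(length(display_color) == 3L)
  out <- array(0, c(nrow(v), ncol(v), 3L))
  for (ch in 1:3) out[, , ch] <- v * display_color[ch]
  out
}

#' Additive composition of pseudocolored layers
#'
#' Per-channel sum of the layers, clipped to 1. Co-expression of a green and
#' a red layer renders yellow; composition is invariant under layer order.
#'
#' @param layers list of RGB arrays of equal dimensions.
#' @param markers,colors optional legend metadata stored on the overlay.
#' @return `overlay_image`.
#' @export
compose_additive <- function(layers, markers = NULL, colors = NULL) {
  if (length(layers) == 0L) stop("compose_additive needs at least one layer")
  dims <- dim(layers[[1]])
  out <- array(0, dims)
  for (l in layers) {
    if (!identical(dim(l), dims)) stop("layers must share dimensions")
    out <- out + l
  }
  overlay_image(out, if (length(layers) == 2L) "two_color" else "multi_pseudocolor",
                markers, colors)
}

#' Default display palette for pseudocolor overlays
#' @param n number of colors needed (up to 3 distinct hues, then recycled).
#' @return list of RGB triples (green, red, purple, ...).
#' @export
overlay_palette <- function(n) {
  base <- list(c(0, 1, 0), c(1, 0, 0), c(0.6, 0, 1))
  rep(base, length.out = n)
}

#' Render one of the standard overlay schemes
#'
#' Dispatches to the three visualization schemes for a registered series:
#' \describe{
#'   \item{`invert_A_over_B`}{invert the first marker's image and multiply it
#'     onto the second marker's image: cells positive only for A appear as
#'     bright spots, co-localized cells are dimmed into the dark background.}
#'   \item{`invert_B_over_A`}{the reverse direction, highlighting cells
#'     positive only for B.}
#'   \item{`two_color`}{recolor the two markers' signal maps (default green
#'     and red) and add them: co-expressing cells render yellow.}
#'   \item{`multi_pseudocolor`}{recolor any number of markers (default
#'     green, red, purple) and add the layers.}
#' }
#'
#' @param scheme scheme name as above.
#' @param images named list of registered, white-balanced [slide_image()]s
#'   (multiplicative schemes).
#' @param signals named list of registered [signal_map()]s (additive
#'   schemes).
#' @param markers markers to use, in scheme order (A then B).
#' @param colors list of RGB triples for the additive schemes; defaults to
#'   [overlay_palette()].
#' @return `overlay_image` with the marker/color legend in its metadata.
#' @export
render_scheme <- function(scheme, images = NULL, signals = NULL,
                          markers = NULL, colors = NULL) {
  get_named <- function(lst, m, what) {
    if (!m %in% names(lst)) stop("marker not available for ", what, ": ", m)
    lst[[m]]
  }
  if (scheme %in% c("invert_A_over_B", "invert_B_over_A")) {
    stopifnot(length(markers) == 2L)
    if (scheme == "invert_B_over_A") markers <- rev(markers)
    a <- get_named(images, markers[1], "inversion")
    b <- get_named(images, markers[2], "base")
    out <- superimpose_multiply(invert_image(a), b)
    out$scheme <- scheme
    out$markers <- markers
    return(out)
  }
  if (scheme %in% c("two_color", "multi_pseudocolor")) {
    if (is.null(markers)) markers <- names(signals)
    if (scheme == "two_color") stopifnot(length(markers) == 2L)
    colors <- colors %||% overlay_palette(length(markers))
    layers <- Map(function(m, col) recolor(get_named(signals, m, "recolor"), col),
                  markers, colors)
    out <- compose_additive(unname(layers), markers, colors)
    out$scheme <- scheme
    return(out)
  }
  stop("unknown overlay scheme: ", scheme)
}
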