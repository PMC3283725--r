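#' One round's brightfield slide scan
#'
#' Container for a single staining round: an RGB raster in `[0, 1]` (origin
#' top-left, x = column, y = row), the marker stained in that round, and an
#' optional blank-slide reference scan used for white balance.
#'
#' @param pixels array `c(rows, cols, 3)` with channels in `[0, 1]`.
#' @param marker marker name.
#' @param round_index staining round (1-based).
#' @param pixel_size_um micron per pixel.
#' @param blank_reference optional RGB array of an unstained blank scan.
#' @return object of class `slide_image`.
#' @export
slide_image <- function(pixels, marker, round_index = 1L, pixel_size_um = 0.5,
                        blank_reference = NULL) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L,
            min(pixels) >= 0, max(pixels) <= 1)
  structure(list(pixels = pixels, marker = marker,
                 round_index = as.integer(round_index),
                 pixel_size_um = pixel_size_um,
                 blank_reference = blank_reference),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("slide_image: %s (round %d), %d x %d px at %g um/px%s\n",
              x$marker, x$round_index, d[2], d[1], x$pixel_size_um,
              if (is.null(x$blank_reference)) "" else ", with blank reference"))
  invisible(x)
}

#' @export
dim.slide_image <- function(x) dim(x$pixels)

# plateau soma profile: 1 inside 0.7 R, cosine taper to 0 at R
soma_kernel <- function(r, R) {
  k <- numeric(length(r))
  k[r <= 0.7 * R] <- 1
  rim <- r > 0.7 * R & r < R
  k[rim] <- 0.5 * (1 + cos(pi * (r[rim] - 0.7 * R) / (0.3 * R)))
  k
}

#' Absorbance field of one marker round
#'
#' The scalar absorbance deposited by the round's staining, before conversion
#' to transmittance: the sum over cells of `expression * stain_density *
#' soma_kernel`, plus Poisson-placed puncta, plus any carried-over absorbance
#' from the previous round. Computed in the ground-truth (unshifted) frame.
#'
#' @param gt [generate_ground_truth()] output.
#' @param marker marker name (must be one of the simulated markers).
#' @param params [sim_params()] object.
#' @param carryover_from optional absorbance matrix of the previous round,
#'   scaled by `params$carryover_fraction` and added.
#' @param include_puncta add sub-cellular puncta clutter (seeded per round).
#' @return absorbance matrix (rows x cols).
#' @export
absorbance_field <- function(gt, marker, params, carryover_from = NULL,
                             include_puncta = TRUE) {
  if (!marker %in% params$markers)
    stop("unknown marker: ", marker)
  dims <- field_dim_px(params)
  A <- matrix(0, dims[1], dims[2])
  px <- params$pixel_size_um

  if (nrow(gt)) {
    for (i in seq_len(nrow(gt))) {
      e <- gt[[marker]][i]
      if (e <= 0) next
      cx <- gt$x_um[i] / px + 0.5
      cy <- gt$y_um[i] / px + 0.5
      R <- gt$radius_um[i] / px
      j0 <- max(1L, floor(cx - R)); j1 <- min(dims[2], ceiling(cx + R))
      i0 <- max(1L, floor(cy - R)); i1 <- min(dims[1], ceiling(cy + R))
      if (j0 > j1 || i0 > i1) next
      ii <- i0:i1; jj <- j0:j1
      r <- sqrt(outer((ii - cy)^2, (jj - cx)^2, `+`))
      A[ii, jj] <- A[ii, jj] +
        e * params$stain_density * soma_kernel(r, R)
    }
  }

  if (include_puncta && params$puncta_density > 0) {
    set.seed(sub_seed(params$seed, paste0("puncta-", marker)))
    area_mm2 <- params$field_width_um * params$field_height_um / 1e6
    n_p <- stats::rpois(1, params$puncta_density * area_mm2)
    if (n_p > 0) {
      px_x <- stats::runif(n_p, 0, params$field_width_um) / px + 0.5
      px_y <- stats::runif(n_p, 0, params$field_height_um) / px + 0.5
      rp <- params$puncta_radius_um / px
      amp <- params$puncta_expression * params$stain_density
      w <- ceiling(rp + 1)
      for (k in seq_len(n_p)) {
        j0 <- max(1L, floor(px_x[k] - w)); j1 <- min(dims[2], ceiling(px_x[k] + w))
        i0 <- max(1L, floor(px_y[k] - w)); i1 <- min(dims[1], ceiling(px_y[k] + w))
        if (j0 > j1 || i0 > i1) next
        ii <- i0:i1; jj <- j0:j1
        d <- sqrt(outer((ii - px_y[k])^2, (jj - px_x[k])^2, `+`))
        # anti-aliased disc: full absorbance in the core, linear falloff over
        # the boundary pixel
        A[ii, jj] <- A[ii, jj] + amp * clip01(rp + 0.5 - d)
      }
    }
  }

  if (!is.null(carryover_from))
    A <- A + params$carryover_fraction * carryover_from
  A
}

# absorbance -> blurred, misaligned, noisy RGB scan
develop_scan <- function(A, transform, params, noise_stream) {
  dims <- dim(A)
  sigma_px <- params$blur_sigma_um / params$pixel_size_um
  pixels <- array(0, c(dims[1], dims[2], 3L))
  for (ch in 1:3) {
    Tch <- exp(-A * params$chromogen_od[ch])
    if (sigma_px > 0 && any(A > 0)) Tch <- gauss_smooth(Tch, sigma_px)
    pixels[, , ch] <- Tch
  }
  pixels <- warp_rigid(pixels, transform, fill = 1)
  for (ch in 1:3) pixels[, , ch] <- pixels[, , ch] * params$illumination[ch]
  if (params$noise_sd > 0) {
    set.seed(sub_seed(params$seed, noise_stream))
    pixels <- pixels + stats::rnorm(length(pixels), 0, params$noise_sd)
  }
  quantize(clip01(pixels), params$bit_depth)
}

render_blank <- function(params, noise_stream) {
  dims <- field_dim_px(params)
  blank <- array(rep(params$illumination, each = prod(dims)),
                 c(dims[1], dims[2], 3L))
  if (params$noise_sd > 0) {
    set.seed(sub_seed(params$seed, noise_stream))
    blank <- blank + stats::rnorm(length(blank), 0, params$noise_sd)
  }
  quantize(clip01(blank), params$bit_depth)
}

#' Render one staining round as a brightfield scan
#'
#' Converts the round's absorbance field to RGB transmittance per channel
#' (`exp(-A * chromogen_od)`, Beer-Lambert against a white blank), applies
#' optical blur, the round's true rigid misalignment (white fill outside the
#' field), the scanner illumination gain, additive Gaussian noise, clipping
#' to `[0, 1]` and bit-depth quantization. A blank reference scan (zero
#' absorbance plus noise) is attached for white balance.
#'
#' @inheritParams absorbance_field
#' @return [slide_image()] with `blank_reference` set.
#' @export
render_round <- function(gt, marker, params, carryover_from = NULL,
                         include_puncta = TRUE) {
  A <- absorbance_field(gt, marker, params, carryover_from, include_puncta)
  round_index <- match(marker, params$markers)
  transform <- attr(gt, "transforms")[[marker]] %||% rigid_transform()
  pixels <- develop_scan(A, transform, params, paste0("noise-", marker))
  blank <- render_blank(params, paste0("blank-", marker))
  img <- slide_image(pixels, marker, round_index, params$pixel_size_um, blank)
  attr(img, "absorbance") <- A
  attr(img, "transform") <- transform
  img
}

#' Render the full multi-round series
#'
#' One scan per marker in round order. Each round carries its own rigid
#' misalignment; with a nonzero `carryover_fraction` each round additionally
#' retains that fraction of the previous round's total absorbance
#' (incomplete stripping).
#'
#' @inheritParams absorbance_field
#' @return named list of [slide_image()] objects, one per marker.
#' @export
render_series <- function(gt, params) {
  prev_A <- NULL
  out <- vector("list", length(params$markers))
  names(out) <- params$markers
  for (m in params$markers) {
    img <- render_round(gt, m, params, carryover_from = prev_A)
    prev_A <- attr(img, "absorbance")
    out[[m]] <- img
  }
  out
}

#' Render a post-strip, secondary-antibody-only control scan
#'
#' The computational analog of the stripping-completeness control: a scan
#' taken after stripping round `after_round`, whose only absorbance is the
#' carried-over fraction of that round's total absorbance. With
#' `carryover_fraction = 0` it is a blank.
#'
#' @inheritParams absorbance_field
#' @param after_round index of the stripped round.
#' @return [slide_image()] with marker `"post-strip"`.
#' @export
render_post_strip <- function(gt, params, after_round = 1L) {
  prev_A <- NULL
  for (r in seq_len(after_round)) {
    prev_A <- absorbance_field(gt, params$markers[r], params,
                               carryover_from = prev_A)
  }
  A <- params$carryover_fraction * prev_A
  pixels <- develop_scan(A, rigid_transform(), params, "noise-post-strip")
  blank <- render_blank(params, "blank-post-strip")
  img <- slide_image(pixels, "post-strip", after_round + 1L,
                     params$pixel_size_um, blank)
  attr(img, "absorbance") <- A
  img
}
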