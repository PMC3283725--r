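#' Build a class table for the slide simulator
#'
#' Each row defines one cell class: a label, the expression level of every
#' marker in `[0, 1]`, and the expected number of cells of that class in the
#' simulated field.
#'
#' @param ... named rows; each value is `list(expr = c(marker = level, ...),
#'   count = n)`, with the name used as the class label.
#' @return data.frame with columns `class`, `count`, and one expression column
#'   per marker.
#' @examples
#' class_table(
#'   "GAD67-only" = list(expr = c(GAD67 = 1, PV = 0), count = 120),
#'   "GAD67+PV"   = list(expr = c(GAD67 = 1, PV = 1), count = 80)
#' )
#' @export
class_table <- function(...) {
  rows <- list(...)
  if (length(rows) == 0L) stop("class_table needs at least one class")
  markers <- names(rows[[1]]$expr)
  out <- do.call(rbind, lapply(names(rows), function(lbl) {
    r <- rows[[lbl]]
    if (!identical(names(r$expr), markers))
      stop("all classes must name the same markers in the same order")
    d <- data.frame(class = lbl, count = r$count, stringsAsFactors = FALSE)
    for (m in markers) d[[m]] <- unname(r$expr[[m]])
    d
  }))
  rownames(out) <- NULL
  out
}

#' Simulation parameters for a multi-round stained-slide series
#'
#' Defines one virtual tissue section and how each staining round of it is
#' rendered as a brightfield RGB scan. The stain model is Beer-Lambert: a
#' cell with expression `e` for the round's marker deposits peak absorbance
#' `e * stain_density` along the unit-less `chromogen_od` color direction, and
#' the pixel transmittance is `exp(-A * chromogen_od)` against a white blank.
#' The default `stain_density` renders a fully expressing soma as effectively
#' opaque -- peak transmittance below the default 8-bit quantization floor in
#' every channel -- matching the visual regime in which fully stained somata
#' vanish exactly into the dark background of a multiplicative overlay;
#' lower values give unsaturated dark-red staining suitable for linear
#' quantification.
#'
#' @param field_width_um,field_height_um physical extent of the field (micron).
#' @param pixel_size_um micron per pixel (scanner resolution; 0.5 is a typical
#'   200x whole-slide scan).
#' @param markers ordered character vector of marker names, one staining round
#'   per marker, in round order.
#' @param classes class table from [class_table()]; its expression columns must
#'   match `markers`.
#' @param cell_radius_um mean soma radius (micron).
#' @param cell_radius_sd_um standard deviation of the soma radius.
#' @param min_spacing_um minimum center-to-center distance between cells;
#'   defaults to two mean radii so somata do not interpenetrate.
#' @param puncta_density sub-cellular puncta ("fine particles") per square mm,
#'   placed independently per round.
#' @param puncta_radius_um punctum radius (micron).
#' @param puncta_expression absorbance of a punctum as a fraction of a fully
#'   expressing soma.
#' @param chromogen_od optical-density direction of the chromogen per unit
#'   absorbance (length-3, unitless); the default is a dark-red,
#'   NOVA-Red-like direction.
#' @param stain_density peak absorbance multiplier at expression 1.
#' @param blur_sigma_um optical blur applied to the transmittance image.
#' @param noise_sd additive Gaussian noise SD on transmittance, added after
#'   blur and clipped with the image.
#' @param illumination scalar or length-3 illumination gain of the scanner
#'   (the blank slide scans at this level); removed by white balance.
#' @param misalignment list of per-round rigid transforms
#'   (see [rigid_transform()]), or `NULL` to draw a small jitter per round
#'   (round 1 identity, later rounds uniform in +/-`jitter_px` and
#'   +/-`jitter_deg`).
#' @param jitter_px,jitter_deg bounds of the automatic inter-round jitter.
#' @param carryover_fraction fraction of the previous round's absorbance
#'   retained by incomplete stripping (0 = complete removal).
#' @param seed RNG seed for the whole simulation.
#' @param bit_depth quantization of rendered rasters in bits per sample
#'   (matching the scanner output); `NULL` for continuous values.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(field_width_um = 1000,
                       field_height_um = 1000,
                       pixel_size_um = 0.5,
                       markers = c("GAD67", "PV"),
                       classes = class_table(
                         "GAD67-only" = list(expr = c(GAD67 = 1, PV = 0), count = 120),
                         "GAD67+PV"   = list(expr = c(GAD67 = 1, PV = 1), count = 80)
                       ),
                       cell_radius_um = 5,
                       cell_radius_sd_um = 0.5,
                       min_spacing_um = 2 * cell_radius_um,
                       puncta_density = 1000,
                       puncta_radius_um = 0.5,
                       puncta_expression = 0.1,
                       chromogen_od = c(0.30, 0.70, 0.65),
                       stain_density = 24,
                       blur_sigma_um = 0.5,
                       noise_sd = 0.01,
                       illumination = 1,
                       misalignment = NULL,
                       jitter_px = 10,
                       jitter_deg = 0.5,
                       carryover_fraction = 0,
                       seed = 1L,
                       bit_depth = 8L) {
  p <- list(
    field_width_um = field_width_um, field_height_um = field_height_um,
    pixel_size_um = pixel_size_um, markers = markers, classes = classes,
    cell_radius_um = cell_radius_um, cell_radius_sd_um = cell_radius_sd_um,
    min_spacing_um = min_spacing_um,
    puncta_density = puncta_density, puncta_radius_um = puncta_radius_um,
    puncta_expression = puncta_expression,
    chromogen_od = chromogen_od, stain_density = stain_density,
    blur_sigma_um = blur_sigma_um, noise_sd = noise_sd,
    illumination = rep_len(illumination, 3L),
    misalignment = misalignment, jitter_px = jitter_px, jitter_deg = jitter_deg,
    carryover_fraction = carryover_fraction, seed = seed, bit_depth = bit_depth
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(
    p$pixel_size_um > 0, p$field_width_um > 0, p$field_height_um > 0,
    length(p$markers) >= 1L, !anyDuplicated(p$markers),
    p$carryover_fraction >= 0, p$carryover_fraction <= 1,
    p$cell_radius_um > 0, p$stain_density > 0,
    length(p$chromogen_od) == 3L, all(p$chromogen_od >= 0),
    p$noise_sd >= 0, all(p$illumination > 0)
  )
  if (!all(p$markers %in% names(p$classes)))
    stop("classes must contain one expression column per marker")
  expr <- as.matrix(p$classes[, p$markers, drop = FALSE])
  if (any(expr < 0) || any(expr > 1))
    stop("expression levels must lie in [0, 1]")
  if (any(p$classes$count < 0)) stop("expected counts must be >= 0")
  if (!is.null(p$misalignment)) {
    if (length(p$misalignment) != length(p$markers))
      stop("misalignment must list one transform per round")
    lapply(p$misalignment, function(t) stopifnot(inherits(t, "rigid_transform")))
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  dims <- field_dim_px(x)
  cat("Stained-slide simulation parameters\n")
  cat(sprintf("  field: %g x %g um at %g um/px (%d x %d px)\n",
              x$field_width_um, x$field_height_um, x$pixel_size_um,
              dims[2], dims[1]))
  cat(sprintf("  rounds: %s\n", paste(x$markers, collapse = ", ")))
  cat(sprintf("  classes: %s (expected %d cells)\n",
              paste(x$classes$class, collapse = ", "), sum(x$classes$count)))
  cat(sprintf("  stain: density %g along OD (%s); noise sd %g; carryover %g\n",
              x$stain_density, paste(x$chromogen_od, collapse = ", "),
              x$noise_sd, x$carryover_fraction))
  invisible(x)
}

# raster dimensions c(rows, cols) of the simulated field
field_dim_px <- function(p) {
  c(round(p$field_height_um / p$pixel_size_um),
    round(p$field_width_um / p$pixel_size_um))
}

#' Three-marker cortical interneuron scenario
#'
#' A ready-made parameter set emulating a sequential GAD67 / parvalbumin /
#' calretinin series over a 4 mm^2 cortical field: every parvalbumin-positive
#' cell also expresses GAD67, parvalbumin and calretinin are disjoint, and
#' parvalbumin marks the largest GAD67 subgroup. Scanned at 1 um/px so that a
#' multi-square-millimeter field stays tractable; pass `pixel_size_um = 0.5`
#' for full scanner resolution on a smaller field.
#'
#' @param ... overrides forwarded to [sim_params()].
#' @return `sim_params` object.
#' @export
sim_params_cortex3 <- function(...) {
  defaults <- list(
    field_width_um = 2000, field_height_um = 2000, pixel_size_um = 1,
    markers = c("GAD67", "PV", "CR"),
    classes = class_table(
      "GAD67-only" = list(expr = c(GAD67 = 1, PV = 0, CR = 0), count = 250),
      "GAD67+PV"   = list(expr = c(GAD67 = 1, PV = 1, CR = 0), count = 180),
      "GAD67+CR"   = list(expr = c(GAD67 = 1, PV = 0, CR = 1), count = 70)
    )
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}
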