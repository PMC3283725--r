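#' Generate the ground-truth cell table for a simulated section
#'
#' Draws the number of cells of each class from a Poisson law around its
#' expected count, then places cell centers uniformly in the field subject to
#' a minimum center-to-center spacing (dart throwing with rejection). Soma
#' radii are Gaussian around the mean radius, truncated below at half the
#' mean. The per-round rigid misalignments of the series are fixed here too,
#' so a ground truth fully determines the geometry of every later rendering.
#'
#' @param params [sim_params()] object.
#' @return data.frame of class `ihc_ground_truth` with columns `cell_id`,
#'   `x_um`, `y_um`, `radius_um`, `class` and one expression column per
#'   marker; attributes `params` and `transforms` (one [rigid_transform()]
#'   per round).
#' @export
generate_ground_truth <- function(params) {
  validate_sim_params(params)
  set.seed(sub_seed(params$seed, "ground-truth"))
  markers <- params$markers
  counts <- stats::rpois(nrow(params$classes), params$classes$count)
  margin <- params$cell_radius_um
  w <- params$field_width_um; h <- params$field_height_um
  if (w <= 2 * margin || h <= 2 * margin)
    stop("field too small to place any cell inside its margins")

  xs <- ys <- numeric(0)
  cls <- character(0)
  min_d2 <- params$min_spacing_um^2
  for (ci in seq_len(nrow(params$classes))) {
    lbl <- params$classes$class[ci]
    for (k in seq_len(counts[ci])) {
      placed <- FALSE
      for (try in seq_len(5000L)) {
        x <- stats::runif(1, margin, w - margin)
        y <- stats::runif(1, margin, h - margin)
        if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= min_d2) {
          xs <- c(xs, x); ys <- c(ys, y); cls <- c(cls, lbl)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf(
          "field too small to place the requested cells at minimum spacing (failed while placing class '%s')",
          lbl))
    }
  }

  n <- length(xs)
  radius <- if (n) pmax(stats::rnorm(n, params$cell_radius_um,
                                     params$cell_radius_sd_um),
                        params$cell_radius_um / 2) else numeric(0)
  gt <- data.frame(cell_id = seq_len(n), x_um = xs, y_um = ys,
                   radius_um = radius, class = cls,
                   stringsAsFactors = FALSE)
  expr <- as.matrix(params$classes[, markers, drop = FALSE])
  rownames(expr) <- params$classes$class
  for (m in markers) gt[[m]] <- if (n) expr[gt$class, m] else numeric(0)

  transforms <- params$misalignment
  if (is.null(transforms)) {
    transforms <- lapply(seq_along(markers), function(r) {
      if (r == 1L) return(rigid_transform(0, 0, 0))
      rigid_transform(stats::runif(1, -params$jitter_px, params$jitter_px),
                      stats::runif(1, -params$jitter_px, params$jitter_px),
                      stats::runif(1, -params$jitter_deg, params$jitter_deg))
    })
  }
  names(transforms) <- markers

  structure(gt, params = params, transforms = transforms,
            class = c("ihc_ground_truth", "data.frame"))
}

#' @export
print.ihc_ground_truth <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Ground truth: %d cells over %g x %g um (%s)\n",
              nrow(x), p$field_width_um, p$field_height_um,
              paste(sprintf("%s: %d", names(table(x$class)), table(x$class)),
                    collapse = ", ")))
  invisible(x)
}

#' Write / read a ground-truth table as TSV
#'
#' The TSV holds one row per cell; simulation parameters and true per-round
#' transforms travel in a JSON sidecar written next to it.
#'
#' @param gt `ihc_ground_truth`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  df <- as.data.frame(gt)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- attr(gt, "params")
  side <- list(
    params = p[setdiff(names(p), c("classes", "misalignment"))],
    classes = attr(gt, "params")$classes,
    transforms = lapply(attr(gt, "transforms"), unclass)
  )
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  class(df) <- c("ihc_ground_truth", "data.frame")
  df
}
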