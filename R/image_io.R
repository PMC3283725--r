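# Raster I/O. Scans travel as 8- or 16-bit RGB TIFF (or PNG); a series is a
# directory of round scans plus blank references and a JSON sidecar naming
# each round's marker and pixel size.

write_raster <- function(pixels, path, bit_depth = 16L) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pixels, path, bits.per.sample = bit_depth)
  } else if (ext == "png") {
    png::writePNG(pixels, path)
  } else stop("unsupported raster format: .", ext)
  invisible(path)
}

read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
        else if (ext == "png") png::readPNG(path)
        else stop("unsupported raster format: .", ext)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px
}

#' Write / read one round's scan
#'
#' The blank reference, when present, is written next to the image as
#' `<name>_blank.<ext>`; marker, round and pixel size go into a JSON sidecar
#' `<name>.json`.
#'
#' @param image [slide_image()].
#' @param path output path (`.tif`/`.tiff` or `.png`).
#' @param bit_depth TIFF bits per sample.
#' @return `path`, invisibly.
#' @export
write_slide_image <- function(image, path, bit_depth = 16L) {
  stopifnot(inherits(image, "slide_image"))
  write_raster(image$pixels, path, bit_depth)
  base <- tools::file_path_sans_ext(path)
  ext <- tools::file_ext(path)
  if (!is.null(image$blank_reference))
    write_raster(image$blank_reference, paste0(base, "_blank.", ext), bit_depth)
  jsonlite::write_json(list(marker = image$marker,
                            round_index = image$round_index,
                            pixel_size_um = image$pixel_size_um),
                       paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_slide_image
#' @export
read_slide_image <- function(path) {
  px <- read_raster(path)
  base <- tools::file_path_sans_ext(path)
  ext <- tools::file_ext(path)
  meta_path <- paste0(base, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(marker = basename(base), round_index = 1L,
                    pixel_size_um = 0.5)
  blank_path <- paste0(base, "_blank.", ext)
  blank <- if (file.exists(blank_path)) read_raster(blank_path) else NULL
  slide_image(px, meta$marker, meta$round_index, meta$pixel_size_um, blank)
}

#' Write / read a rendered series
#'
#' Writes one TIFF per round (`round1_<marker>.tif`, ...) with blank
#' references and sidecars, plus the ground truth when given.
#'
#' @param series named list of [slide_image()]s from [render_series()].
#' @param dir output directory (created if needed).
#' @param gt optional ground truth written as `ground_truth.tsv`.
#' @param bit_depth TIFF bits per sample.
#' @return character vector of the image paths, invisibly.
#' @export
write_series <- function(series, dir, gt = NULL, bit_depth = 16L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(series), function(r) {
    img <- series[[r]]
    p <- file.path(dir, sprintf("round%d_%s.tif", img$round_index, img$marker))
    write_slide_image(img, p, bit_depth)
    p
  }, character(1))
  if (!is.null(gt)) write_ground_truth(gt, file.path(dir, "ground_truth.tsv"))
  invisible(paths)
}

#' @rdname write_series
#' @export
read_series <- function(dir) {
  paths <- sort(list.files(dir, pattern = "^round[0-9]+_.*\\.(tif|tiff|png)$",
                           full.names = TRUE))
  paths <- paths[!grepl("_blank\\.", paths)]
  if (!length(paths)) stop("no round images found in ", dir)
  series <- lapply(paths, read_slide_image)
  series <- series[order(vapply(series, `[[`, integer(1), "round_index"))]
  names(series) <- vapply(series, `[[`, character(1), "marker")
  series
}

#' Write a signal map as a 16-bit grayscale TIFF
#'
#' @param map [signal_map()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_signal_map <- function(map, path) {
  stopifnot(inherits(map, "signal_map"))
  tiff::writeTIFF(map$values, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write an overlay as an 8-bit RGB image with a JSON legend sidecar
#'
#' @param overlay `overlay_image` from the overlay operations.
#' @param path output `.png` or `.tif` path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(overlay, path) {
  write_raster(overlay$pixels, path, bit_depth = 8L)
  jsonlite::write_json(list(scheme = overlay$scheme, markers = overlay$markers,
                            colors = overlay$colors),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write cell records as TSV
#'
#' One row per cell record with a stable column order and fixed numeric
#' formatting, so identical analyses produce byte-identical tables.
#'
#' @param records [quantify_cells()] output.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cell_records <- function(records, path) {
  df <- as.data.frame(records)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
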