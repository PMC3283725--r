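# Cell-scale object detection on signal maps, cross-marker merging,
# per-cell quantification and co-expression classification.

#' Detection parameters
#'
#' @param soma_radius_um nominal soma radius; detection smooths at half this
#'   radius and quantification discs default to it.
#' @param min_radius_um,max_radius_um accepted soma radius band; connected
#'   components with area outside the corresponding disc areas are discarded
#'   (this is the puncta / debris filter).
#' @param k_mad threshold multiplier: threshold = background median +
#'   `k_mad` * MAD, with background statistics taken robustly over the raw
#'   (unsmoothed) map.
#' @param min_signal floor on the threshold, in signal units; signals below a
#'   few percent of full scale are not separable from calibration residue.
#' @param threshold fixed absolute threshold overriding the robust rule, or
#'   `NULL`.
#' @param watershed_tolerance intensity depth (signal units) a local maximum
#'   must have to split a connected component into separate somata; abutting
#'   cells form one component, and the watershed separates them at the
#'   intensity saddle.
#' @return list of class `detect_params`.
#' @export
detect_params <- function(soma_radius_um = 5, min_radius_um = 2.5,
                          max_radius_um = 10, k_mad = 5, min_signal = 0.05,
                          threshold = NULL, watershed_tolerance = 0.3) {
  structure(list(soma_radius_um = soma_radius_um,
                 min_radius_um = min_radius_um, max_radius_um = max_radius_um,
                 k_mad = k_mad, min_signal = min_signal, threshold = threshold,
                 watershed_tolerance = watershed_tolerance),
            class = "detect_params")
}

#' Detect cell-scale objects in a signal map
#'
#' Smooths the map with a Gaussian of half the nominal soma radius,
#' thresholds it at the robust background level (median + `k_mad` * MAD of
#' the raw map, floored at `min_signal`), labels connected components, splits
#' components holding several intensity maxima by a watershed, and discards
#' segments whose area falls outside the configured soma-area band --
#' rejecting both sub-cellular puncta and oversized debris. Centroids are
#' intensity-weighted on the smoothed map.
#'
#' @param signal [signal_map()] in the reference frame.
#' @param params [detect_params()].
#' @return data.frame with one row per detection: `x_px`, `y_px`, `x_um`,
#'   `y_um`, `area_px`, `mean_signal`, `marker`; attribute `threshold`.
#' @export
detect_cells <- function(signal, params = detect_params()) {
  stopifnot(inherits(signal, "signal_map"), inherits(params, "detect_params"))
  v <- signal$values
  px <- signal$pixel_size_um
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      area_px = numeric(0), mean_signal = numeric(0),
                      marker = character(0), stringsAsFactors = FALSE)
  if (max(v) == 0) return(structure(empty, threshold = NA_real_))

  if (is.null(params$threshold)) {
    bg <- robust_bg(v)
    tau <- max(bg$median + params$k_mad * bg$mad, params$min_signal)
  } else tau <- params$threshold

  sm <- gauss_smooth(v, params$soma_radius_um / 2 / px)
  mask <- sm > tau
  if (!any(mask)) return(structure(empty, threshold = tau))

  labels <- EBImage::watershed(EBImage::as.Image(sm * mask),
                               tolerance = params$watershed_tolerance, ext = 1)
  labels <- as.matrix(EBImage::imageData(labels))

  lab <- as.integer(labels)
  keep <- lab > 0L
  lab <- lab[keep]
  w <- sm[keep]
  raw <- v[keep]
  idx <- which(keep)
  nr <- nrow(v)
  yy <- (idx - 1L) %% nr + 1L
  xx <- (idx - 1L) %/% nr + 1L

  area <- tabulate(lab)
  sw <- rowsum(w, lab)[, 1]
  cx <- rowsum(w * xx, lab)[, 1] / sw
  cy <- rowsum(w * yy, lab)[, 1] / sw
  msig <- rowsum(raw, lab)[, 1] / area

  a_min <- pi * (params$min_radius_um / px)^2
  a_max <- pi * (params$max_radius_um / px)^2
  ok <- area >= a_min & area <= a_max
  if (!any(ok)) return(structure(empty, threshold = tau))
  out <- data.frame(x_px = cx[ok], y_px = cy[ok],
                    x_um = (cx[ok] - 0.5) * px, y_um = (cy[ok] - 0.5) * px,
                    area_px = area[ok], mean_signal = msig[ok],
                    marker = signal$marker, stringsAsFactors = FALSE)
  ord <- order(out$y_um, out$x_um)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = tau)
}

#' Merge detections across markers into candidate cells
#'
#' Pools per-marker detections and clusters them by single linkage at the
#' merge radius; each cluster becomes one candidate cell at the mean position
#' of its members. Output rows are ordered by (y, x) so merging is
#' independent of marker order.
#'
#' @param detections list of [detect_cells()] data frames (one per marker).
#' @param merge_radius_um single-linkage cut distance (micron).
#' @return data.frame with `cell_id`, `x_um`, `y_um`, `n_detections`,
#'   `markers` (comma-joined contributing markers).
#' @export
merge_detections <- function(detections, merge_radius_um = 5) {
  all <- do.call(rbind, detections)
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(cell_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), n_detections = integer(0),
                      markers = character(0), stringsAsFactors = FALSE))
  if (nrow(all) == 1L) {
    grp <- 1L
  } else {
    hc <- stats::hclust(stats::dist(all[, c("x_um", "y_um")]),
                        method = "single")
    grp <- stats::cutree(hc, h = merge_radius_um)
  }
  cx <- tapply(all$x_um, grp, mean)
  cy <- tapply(all$y_um, grp, mean)
  nd <- tapply(all$x_um, grp, length)
  mk <- tapply(all$marker, grp, function(m) paste(sort(unique(m)), collapse = ","))
  out <- data.frame(x_um = as.numeric(cx), y_um = as.numeric(cy),
                    n_detections = as.integer(nd), markers = as.character(mk),
                    stringsAsFactors = FALSE)
  out <- out[order(out$y_um, out$x_um), , drop = FALSE]
  out$cell_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("cell_id", "x_um", "y_um", "n_detections", "markers")]
}

#' Quantify merged cells across all marker maps
#'
#' For every candidate cell, measures the mean signal of each marker over a
#' disc at the cell position (a 10 percent trimmed mean, so a few stray
#' punctum pixels inside the disc cannot masquerade as somatic stain), calls
#' the marker positive when the disc mean reaches that map's robust
#' positivity threshold (background median + `pos_k` * MAD, floored at
#' `pos_floor`), labels the cell by its positive marker combination, and, in
#' a second pass, expresses each disc mean relative to the average disc mean
#' of all cells positive for that marker.
#'
#' @param cells [merge_detections()] output.
#' @param signals named list of registered [signal_map()]s, one per marker.
#' @param disc_radius_um sampling disc radius (default: nominal soma radius).
#' @param pos_k MAD multiplier of the positivity threshold.
#' @param pos_floor threshold floor in signal units.
#' @param disc_trim trim fraction of the disc mean (see [disc_mean()]).
#' @return data.frame of cell records: `record_id`, `x_um`, `y_um`, one
#'   `<marker>_signal`, `<marker>_pos` and `<marker>_rel` column per marker,
#'   and `class`; attribute `pos_thresholds`.
#' @export
quantify_cells <- function(cells, signals, disc_radius_um = 5, pos_k = 5,
                           pos_floor = 0.02, disc_trim = 0.1) {
  markers <- names(signals)
  stopifnot(length(markers) >= 1L, !is.null(markers))
  thresholds <- vapply(signals, function(s) {
    bg <- robust_bg(s$values)
    max(bg$median + pos_k * bg$mad, pos_floor)
  }, numeric(1))

  n <- nrow(cells)
  rec <- data.frame(record_id = seq_len(n), x_um = cells$x_um,
                    y_um = cells$y_um, stringsAsFactors = FALSE)
  for (m in markers) {
    s <- signals[[m]]
    r_px <- disc_radius_um / s$pixel_size_um
    vals <- vapply(seq_len(n), function(i) {
      disc_mean(s$values, cells$x_um[i] / s$pixel_size_um + 0.5,
                cells$y_um[i] / s$pixel_size_um + 0.5, r_px, trim = disc_trim)
    }, numeric(1))
    rec[[paste0(m, "_signal")]] <- vals
    rec[[paste0(m, "_pos")]] <- vals >= thresholds[[m]]
  }
  flags <- as.matrix(rec[, paste0(markers, "_pos"), drop = FALSE])
  rec$class <- apply(flags, 1, function(f) {
    if (!any(f)) "none" else paste(markers[f], collapse = "+")
  })
  if (n == 0L) rec$class <- character(0)
  for (m in markers) {
    pos <- rec[[paste0(m, "_pos")]]
    denom <- if (any(pos)) mean(rec[[paste0(m, "_signal")]][pos]) else NA_real_
    rec[[paste0(m, "_rel")]] <- rec[[paste0(m, "_signal")]] / denom
  }
  structure(rec, pos_thresholds = thresholds, markers = markers)
}

#' Summarize cell records into a co-localization report
#'
#' Counts records per co-expression class, totals per marker, and for every
#' ordered marker pair (X, Y) the fraction of X-positive records that are
#' also Y-positive (NA when no record is X-positive).
#'
#' @param records [quantify_cells()] output.
#' @param markers marker names; defaults to those recorded on `records`.
#' @param qc optional named list of QC entries carried into the report.
#' @param parameters optional named list of run parameters carried into the
#'   report.
#' @return object of class `coloc_report` with fields `n_records`,
#'   `class_counts`, `marker_totals`, `conditional_fractions` (matrix
#'   fraction[X, Y] = P(Y+ | X+)), `qc`, `parameters`.
#' @export
summarize_coloc <- function(records, markers = NULL, qc = NULL,
                            parameters = NULL) {
  markers <- markers %||% attr(records, "markers")
  if (is.null(markers)) stop("marker names are required")
  n <- nrow(records)
  class_counts <- if (n) table(records$class) else table(character(0))
  flags <- as.matrix(records[, paste0(markers, "_pos"), drop = FALSE])
  colnames(flags) <- markers
  totals <- if (n) colSums(flags) else stats::setNames(rep(0L, length(markers)), markers)
  frac <- matrix(NA_real_, length(markers), length(markers),
                 dimnames = list(markers, markers))
  for (a in markers) for (b in markers) {
    if (a == b) next
    na <- sum(flags[, a])
    frac[a, b] <- if (na > 0) sum(flags[, a] & flags[, b]) / na else NA_real_
  }
  structure(list(n_records = n,
                 class_counts = as.list(class_counts),
                 marker_totals = as.list(totals),
                 conditional_fractions = frac,
                 pos_thresholds = attr(records, "pos_thresholds"),
                 qc = qc, parameters = parameters),
            class = "coloc_report")
}

#' @export
print.coloc_report <- function(x, ...) {
  cat(sprintf("Co-localization report: %d cell records\n", x$n_records))
  if (length(x$class_counts)) {
    cat("  classes:\n")
    for (cl in names(x$class_counts))
      cat(sprintf("    %-16s %d\n", cl, x$class_counts[[cl]]))
  }
  mk <- rownames(x$conditional_fractions)
  for (a in mk) for (b in mk) {
    f <- x$conditional_fractions[a, b]
    if (!is.na(f))
      cat(sprintf("  fraction of %s+ cells also %s+: %.3f\n", a, b, f))
  }
  invisible(x)
}

#' Match detections or records against planted ground truth
#'
#' Greedy nearest-neighbor one-to-one matching within a match radius, the
#' standard evaluation oracle for simulated fields.
#'
#' @param detected data.frame with `x_um`, `y_um`.
#' @param truth data.frame with `x_um`, `y_um` (e.g. a ground-truth table,
#'   possibly filtered to cells expressing the relevant marker).
#' @param match_radius_um maximum allowed center distance.
#' @return list with `recall`, `precision`, `n_matched`, and the matched
#'   index pairs.
#' @export
match_to_truth <- function(detected, truth, match_radius_um = 5) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0L || nt == 0L)
    return(list(recall = if (nt) 0 else NA_real_,
                precision = if (nd) 0 else NA_real_,
                n_matched = 0L, pairs = cbind(integer(0), integer(0))))
  d2 <- outer(detected$x_um, truth$x_um, `-`)^2 +
        outer(detected$y_um, truth$y_um, `-`)^2
  lim <- match_radius_um^2
  pairs <- NULL
  used_d <- logical(nd); used_t <- logical(nt)
  ord <- order(d2)
  for (k in ord) {
    if (d2[k] > lim) break
    i <- (k - 1L) %% nd + 1L
    j <- (k - 1L) %/% nd + 1L
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE; used_t[j] <- TRUE
    pairs <- rbind(pairs, c(i, j))
  }
  nm <- sum(used_t)
  list(recall = nm / nt, precision = nm / nd, n_matched = nm,
       pairs = pairs %||% cbind(integer(0), integer(0)))
}
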