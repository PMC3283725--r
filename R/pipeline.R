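#' Configuration of an end-to-end analysis run
#'
#' @param mode `"simulate"` (render a virtual series from `sim`) or
#'   `"files"` (read a scanned series from `image_paths`).
#' @param sim [sim_params()] for simulate mode; its seed is replaced by the
#'   run `seed` so one seed drives the whole run.
#' @param image_paths character vector of round image paths (files mode);
#'   each image's JSON sidecar supplies its marker and pixel size.
#' @param post_strip_path optional path of a post-strip control scan
#'   (files mode QC).
#' @param signal_mode signal extraction mode, see [extract_signal()].
#' @param chromogen_od chromogen OD direction for deconvolution mode.
#' @param register estimate and undo inter-round misalignment.
#' @param reference_round round used as the registration reference frame.
#' @param theta_range rotation search half-range (degrees).
#' @param overlays list of overlay requests, each
#'   `list(scheme =, markers =, colors = NULL)`; `NULL` for a default set
#'   (scheme A on the first two markers plus a multi-marker pseudocolor
#'   composite).
#' @param detect [detect_params()].
#' @param merge_radius_um cross-marker merge radius.
#' @param disc_radius_um quantification disc radius.
#' @param pos_k,pos_floor positivity threshold parameters, see
#'   [quantify_cells()].
#' @param qc run the stripping QC (simulate mode renders a post-strip
#'   control after round 1 using the simulation's `carryover_fraction`).
#' @param qc_f_max failing residual fraction, see [assess_stripping()].
#' @param output_dir directory for written artifacts (overlays, cell table,
#'   report, log), or `NULL` to skip writing.
#' @param seed run seed; every random stage draws from a stream derived
#'   from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "files"),
                       sim = sim_params(),
                       image_paths = NULL,
                       post_strip_path = NULL,
                       signal_mode = "inverted_luminance",
                       chromogen_od = c(0.30, 0.70, 0.65),
                       register = TRUE,
                       reference_round = 1L,
                       theta_range = 3,
                       overlays = NULL,
                       detect = detect_params(),
                       merge_radius_um = 5,
                       disc_radius_um = detect$soma_radius_um,
                       pos_k = 5,
                       pos_floor = 0.02,
                       qc = TRUE,
                       qc_f_max = 0.001,
                       output_dir = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(image_paths))
    stop("files mode needs image_paths")
  structure(list(mode = mode, sim = sim, image_paths = image_paths,
                 post_strip_path = post_strip_path,
                 signal_mode = signal_mode, chromogen_od = chromogen_od,
                 register = register, reference_round = reference_round,
                 theta_range = theta_range, overlays = overlays,
                 detect = detect, merge_radius_um = merge_radius_um,
                 disc_radius_um = disc_radius_um, pos_k = pos_k,
                 pos_floor = pos_floor, qc = qc, qc_f_max = qc_f_max,
                 output_dir = output_dir, seed = seed),
            class = "run_config")
}

config_parameters <- function(config) {
  keep <- c("mode", "signal_mode", "register", "reference_round",
            "theta_range", "merge_radius_um", "disc_radius_um", "pos_k",
            "pos_floor", "qc", "qc_f_max", "seed")
  c(config[keep], list(detect = unclass(config$detect)))
}

#' Run the full sequential-staining analysis pipeline
#'
#' Orchestrates the chain scan acquisition (simulated or from files) ->
#' blank-slide white balance -> signal extraction -> rigid registration to
#' the reference round -> requested overlays -> cell detection, cross-marker
#' merging, quantification and co-localization summary -> stripping QC, and
#' optionally writes every artifact (overlays, cell TSV, report JSON, log).
#' Rerunning with an identical configuration and seed reproduces the cell
#' table byte-for-byte.
#'
#' @param config [run_config()].
#' @return list of class `pipeline_result`: `report` ([summarize_coloc()]
#'   output with QC attached), `records`, `cells`, `signals` (registered
#'   maps), `overlays`, `transforms` (estimated per round), `qc`, and in
#'   simulate mode `ground_truth` and `true_transforms`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message("[seqihc] ", msg)
  }

  gt <- NULL
  if (config$mode == "simulate") {
    sim <- config$sim
    sim$seed <- config$seed
    say("simulating series: %d markers, seed %s",
        length(sim$markers), format(config$seed))
    gt <- generate_ground_truth(sim)
    series <- render_series(gt, sim)
  } else {
    say("reading %d round images", length(config$image_paths))
    series <- lapply(config$image_paths, read_slide_image)
    series <- series[order(vapply(series, `[[`, integer(1), "round_index"))]
    names(series) <- vapply(series, `[[`, character(1), "marker")
  }
  markers <- names(series)
  dims <- lapply(series, function(im) dim(im$pixels))
  if (length(unique(dims)) != 1L)
    stop("round images do not share dimensions; cannot analyze the series")

  say("white balance + signal extraction (%s)", config$signal_mode)
  wb <- lapply(series, white_balance)
  signals <- lapply(wb, extract_signal, mode = config$signal_mode,
                    chromogen_od = config$chromogen_od)

  ref_i <- config$reference_round
  transforms <- stats::setNames(vector("list", length(markers)), markers)
  for (r in seq_along(markers)) {
    if (!config$register || r == ref_i) {
      transforms[[r]] <- rigid_transform(0, 0, 0)
      signals[[r]]$frame <- "reference"
      next
    }
    t_hat <- estimate_rigid(signals[[ref_i]], signals[[r]],
                            theta_range = config$theta_range)
    transforms[[r]] <- t_hat
    inv <- rt_invert(t_hat)
    signals[[r]] <- warp_rigid(signals[[r]], inv)
    wb[[r]] <- warp_rigid(wb[[r]], inv, fill = 1)
    say("registered round %d (%s): dx %.2f, dy %.2f, theta %.3f deg",
        r, markers[r], t_hat$dx_px, t_hat$dy_px, t_hat$theta_deg)
  }

  overlay_specs <- config$overlays
  if (is.null(overlay_specs)) {
    overlay_specs <- list()
    if (length(markers) >= 2L)
      overlay_specs <- list(
        list(scheme = "invert_A_over_B", markers = markers[1:2]),
        list(scheme = "multi_pseudocolor", markers = markers))
  }
  overlays <- lapply(overlay_specs, function(sp)
    render_scheme(sp$scheme, images = wb, signals = signals,
                  markers = sp$markers, colors = sp$colors))

  say("detecting cells on %d maps", length(signals))
  detections <- lapply(signals, detect_cells, params = config$detect)
  cells <- merge_detections(detections, config$merge_radius_um)
  say("%d merged candidate cells", nrow(cells))
  records <- quantify_cells(cells, signals,
                            disc_radius_um = config$disc_radius_um,
                            pos_k = config$pos_k, pos_floor = config$pos_floor)

  qc_res <- NULL
  if (isTRUE(config$qc)) {
    post <- NULL
    if (config$mode == "simulate") {
      sim <- config$sim; sim$seed <- config$seed
      post <- render_post_strip(gt, sim, after_round = 1L)
    } else if (!is.null(config$post_strip_path)) {
      post <- read_slide_image(config$post_strip_path)
    }
    if (!is.null(post)) {
      qc_res <- assess_stripping(post, previous_round_map = signals[[1]],
                                 f_max = config$qc_f_max,
                                 signal_mode = config$signal_mode)
      say("stripping QC: %s (residual fraction %.3e)", qc_res$verdict,
          qc_res$residual_fraction)
    }
  }

  qc_block <- list(
    registration = lapply(transforms, unclass),
    stripping = if (!is.null(qc_res)) unclass(qc_res) else NULL)
  report <- summarize_coloc(records, markers, qc = qc_block,
                            parameters = config_parameters(config))

  result <- structure(list(report = report, records = records, cells = cells,
                           signals = signals, overlays = overlays,
                           transforms = transforms, qc = qc_res,
                           ground_truth = gt,
                           true_transforms = if (!is.null(gt)) attr(gt, "transforms"),
                           log = log_lines),
                      class = "pipeline_result")

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_cell_records(records, file.path(out, "cells.tsv"))
    for (k in seq_along(overlays))
      write_overlay(overlays[[k]],
                    file.path(out, sprintf("overlay_%d_%s.png", k,
                                           overlays[[k]]$scheme)))
    jsonlite::write_json(report_to_list(report),
                         file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    if (!is.null(gt)) write_ground_truth(gt, file.path(out, "ground_truth.tsv"))
    writeLines(log_lines, file.path(out, "run.log"))
    say("artifacts written to %s", out)
  }
  say("pipeline finished in %.1f s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  if (!is.null(x$qc)) print(x$qc)
  invisible(x)
}

# plain-list view of a report for JSON serialization
report_to_list <- function(report) {
  frac <- report$conditional_fractions
  frac_list <- list()
  for (a in rownames(frac)) {
    frac_list[[a]] <- as.list(frac[a, setdiff(colnames(frac), a)])
  }
  list(n_records = report$n_records,
       class_counts = report$class_counts,
       marker_totals = report$marker_totals,
       conditional_fractions = frac_list,
       pos_thresholds = as.list(report$pos_thresholds),
       qc = report$qc,
       parameters = report$parameters)
}
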