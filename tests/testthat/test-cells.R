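planted_two_marker <- function() {
  p <- sim_params(field_width_um = 300, field_height_um = 300,
                  pixel_size_um = 1, puncta_density = 500,
                  classes = class_table(
                    "only" = list(expr = c(GAD67 = 1, PV = 0), count = 0),
                    "both" = list(expr = c(GAD67 = 1, PV = 1), count = 0)),
                  misalignment = list(rigid_transform(), rigid_transform()),
                  seed = 11L)
  x <- c(60, 150, 240, 100, 200)
  y <- c(60, 80, 70, 200, 220)
  gt <- manual_gt(p, x, y, radius_um = 5,
                  class = c("only", "only", "only", "both", "both"),
                  expr = list(GAD67 = rep(1, 5), PV = c(0, 0, 0, 1, 1)))
  list(p = p, gt = gt)
}

analyze_series <- function(gt, p) {
  series <- render_series(gt, p)
  wb <- lapply(series, white_balance)
  signals <- lapply(wb, extract_signal)
  for (m in names(signals)) signals[[m]]$frame <- "reference"
  signals
}

test_that("detection finds planted somata and nothing in empty maps", {
  fx <- planted_two_marker()
  signals <- analyze_series(fx$gt, fx$p)

  det_g <- detect_cells(signals$GAD67)
  expect_identical(nrow(det_g), 5L)
  m <- match_to_truth(det_g, as.data.frame(fx$gt))
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  # centroid accuracy well inside a soma radius
  expect_lt(max(sqrt((det_g$x_um[m$pairs[, 1]] - fx$gt$x_um[m$pairs[, 2]])^2 +
                     (det_g$y_um[m$pairs[, 1]] - fx$gt$y_um[m$pairs[, 2]])^2)),
            1.5)

  det_p <- detect_cells(signals$PV)
  expect_identical(nrow(det_p), 2L)

  # all-zero map: no detections
  empty <- signal_map(matrix(0, 100, 100), "x", 1)
  expect_identical(nrow(detect_cells(empty)), 0L)
})

test_that("a puncta-only field yields zero cell detections", {
  p <- sim_params(field_width_um = 300, field_height_um = 300,
                  pixel_size_um = 1, puncta_density = 2000,
                  classes = class_table(
                    "c" = list(expr = c(GAD67 = 1, PV = 0), count = 0)),
                  misalignment = list(rigid_transform(), rigid_transform()),
                  seed = 3L)
  gt <- generate_ground_truth(p)
  expect_identical(nrow(gt), 0L)
  signals <- analyze_series(gt, p)
  expect_identical(nrow(detect_cells(signals$GAD67)), 0L)
})

test_that("merging pools detections across markers at the merge radius", {
  d1 <- data.frame(x_px = 1, y_px = 1, x_um = c(10, 50), y_um = c(10, 50),
                   area_px = 80, mean_signal = 0.5, marker = "A")
  d2 <- data.frame(x_px = 1, y_px = 1, x_um = c(12, 90), y_um = c(11, 90),
                   area_px = 80, mean_signal = 0.5, marker = "B")
  cells <- merge_detections(list(d1, d2), merge_radius_um = 5)
  expect_identical(nrow(cells), 3L)
  expect_identical(cells$n_detections[order(cells$x_um)], c(2L, 1L, 1L))
  expect_setequal(cells$markers, c("A,B", "A", "B"))
  # the merged cell sits at the mean of its members
  merged <- cells[cells$n_detections == 2L, ]
  expect_equal(merged$x_um, 11)
  expect_equal(merged$y_um, 10.5)

  # marker order does not change the result
  cells_rev <- merge_detections(list(d2, d1), merge_radius_um = 5)
  expect_equal(cells[, c("x_um", "y_um", "n_detections")],
               cells_rev[, c("x_um", "y_um", "n_detections")])

  expect_identical(nrow(merge_detections(list())), 0L)
  expect_identical(nrow(merge_detections(list(d1[0, ]))), 0L)
})

test_that("quantification recovers planted co-expression classes", {
  fx <- planted_two_marker()
  signals <- analyze_series(fx$gt, fx$p)
  detections <- lapply(signals, detect_cells)
  cells <- merge_detections(detections)
  expect_identical(nrow(cells), 5L)
  rec <- quantify_cells(cells, signals)
  expect_identical(sort(rec$class), sort(c(rep("GAD67", 3), rep("GAD67+PV", 2))))
  rep_ <- summarize_coloc(rec)
  expect_equal(rep_$conditional_fractions["PV", "GAD67"], 1)
  expect_equal(rep_$conditional_fractions["GAD67", "PV"], 2 / 5)
  expect_identical(rep_$n_records, 5L)
  expect_identical(rep_$marker_totals$GAD67, 5)
})

test_that("relative expression reflects planted expression ratios", {
  p <- sim_params(field_width_um = 300, field_height_um = 300,
                  pixel_size_um = 1, noise_sd = 0, puncta_density = 0,
                  stain_density = 1.5, bit_depth = NULL,
                  classes = class_table(
                    "hi" = list(expr = c(GAD67 = 1, PV = 0), count = 0),
                    "lo" = list(expr = c(GAD67 = 0.5, PV = 0), count = 0)),
                  misalignment = list(rigid_transform(), rigid_transform()))
  gt <- manual_gt(p, x_um = c(80, 80, 220, 220), y_um = c(80, 220, 80, 220),
                  radius_um = 6, class = c("hi", "hi", "lo", "lo"),
                  expr = list(GAD67 = c(1, 1, 0.5, 0.5), PV = rep(0, 4)))
  series <- render_series(gt, p)
  wb <- lapply(series, white_balance)
  signals <- lapply(wb, extract_signal, mode = "deconvolution")
  for (m in names(signals)) signals[[m]]$frame <- "reference"
  det <- lapply(signals, detect_cells)
  cells <- merge_detections(det)
  rec <- quantify_cells(cells, signals)
  hi <- rec$GAD67_signal[rec$x_um < 150]
  lo <- rec$GAD67_signal[rec$x_um > 150]
  expect_equal(mean(hi) / mean(lo), 2, tolerance = 0.1)
  # relative expression normalizes to the positive-cell mean
  expect_equal(mean(rec$GAD67_rel[rec$GAD67_pos]), 1, tolerance = 1e-10)
})

test_that("greedy truth matching is one-to-one and radius-limited", {
  truth <- data.frame(x_um = c(10, 30), y_um = c(10, 30))
  det <- data.frame(x_um = c(10.5, 10.8, 100), y_um = c(10.2, 10.1, 100))
  m <- match_to_truth(det, truth, match_radius_um = 5)
  expect_identical(m$n_matched, 1L)       # second detection can't reuse cell 1
  expect_equal(m$recall, 0.5)
  expect_equal(m$precision, 1 / 3)
  m0 <- match_to_truth(det[0, ], truth)
  expect_equal(m0$recall, 0)
})
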