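test_that("ground truth generation honors counts, spacing and determinism", {
  p <- small_params()

  zero <- sim_params(
    field_width_um = 300, field_height_um = 300, pixel_size_um = 1,
    classes = class_table("empty" = list(expr = c(GAD67 = 0, PV = 0), count = 0))
  )
  expect_identical(nrow(generate_ground_truth(zero)), 0L)

  gt1 <- generate_ground_truth(p)
  gt2 <- generate_ground_truth(p)
  expect_identical(as.data.frame(gt1), as.data.frame(gt2))

  expect_true(all(gt1$x_um > 0 & gt1$x_um < p$field_width_um))
  expect_true(all(gt1$y_um > 0 & gt1$y_um < p$field_height_um))
  expect_false(anyDuplicated(gt1$cell_id) > 0)
  if (nrow(gt1) > 1) {
    d <- as.matrix(dist(cbind(gt1$x_um, gt1$y_um)))
    diag(d) <- Inf
    expect_gte(min(d), p$min_spacing_um)
  }
  # expression vectors follow the class table
  expect_true(all(gt1$GAD67 == 1))
  expect_true(all((gt1$class == "GAD67+PV") == (gt1$PV == 1)))
})

test_that("realized cell counts are Poisson around the expected count", {
  counts <- vapply(1:200, function(s) {
    p <- sim_params(field_width_um = 1000, field_height_um = 1000,
                    classes = class_table(
                      "a" = list(expr = c(GAD67 = 1, PV = 0), count = 50)),
                    seed = s)
    nrow(generate_ground_truth(p))
  }, numeric(1))
  se <- sqrt(50 / 200)
  expect_lt(abs(mean(counts) - 50), 3 * se)
})

test_that("an overcrowded field fails with the limiting class named", {
  p <- sim_params(field_width_um = 60, field_height_um = 60,
                  classes = class_table(
                    "dense" = list(expr = c(GAD67 = 1, PV = 0), count = 500)))
  expect_error(generate_ground_truth(p), "dense")
})

test_that("rendering follows the Beer-Lambert closed form", {
  p <- sim_params(field_width_um = 100, field_height_um = 100,
                  pixel_size_um = 0.5, noise_sd = 0, blur_sigma_um = 0,
                  stain_density = 1, bit_depth = NULL, puncta_density = 0,
                  classes = class_table(
                    "c" = list(expr = c(GAD67 = 1, PV = 0), count = 0)),
                  misalignment = list(rigid_transform(), rigid_transform()))
  gt_empty <- generate_ground_truth(p)

  # empty tissue renders pure white
  blank_img <- render_round(gt_empty, "GAD67", p)
  expect_equal(range(blank_img$pixels), c(1, 1))

  gt1 <- manual_gt(p, 50, 50, 8, "c", list(GAD67 = 1, PV = 0))
  img <- render_round(gt1, "GAD67", p)
  # center pixel: transmittance exp(-od) at unit absorbance
  expect_equal(img$pixels[101, 101, ], exp(-c(0.30, 0.70, 0.65)),
               tolerance = 1e-6)

  # expression 0 for the round's marker renders like empty tissue
  img_pv <- render_round(gt1, "PV", p)
  expect_identical(img_pv$pixels, blank_img$pixels)

  expect_error(render_round(gt1, "nope", p), "unknown marker")
})

test_that("carryover adds the configured fraction of the previous round", {
  p <- sim_params(field_width_um = 120, field_height_um = 120,
                  pixel_size_um = 1, noise_sd = 0, blur_sigma_um = 0,
                  stain_density = 2, puncta_density = 0,
                  carryover_fraction = 0.05,
                  classes = class_table(
                    "c" = list(expr = c(GAD67 = 1, PV = 0), count = 0)),
                  misalignment = list(rigid_transform(), rigid_transform()))
  gt <- manual_gt(p, 60, 60, 8, "c", list(GAD67 = 1, PV = 0))
  A1 <- absorbance_field(gt, "GAD67", p)
  A2 <- absorbance_field(gt, "PV", p, carryover_from = A1)
  expect_equal(A2, 0.05 * A1)

  # and through the rendered series: round-2 transmittance at the cell
  # follows the carried-over absorbance analytically
  series <- render_series(gt, p)
  expect_equal(series$PV$pixels[61, 61, ],
               exp(-0.05 * A1[61, 61] * p$chromogen_od), tolerance = 1e-2)
})

test_that("series rendering is deterministic, bounded, and monotone in expression", {
  p <- small_params()
  gt <- generate_ground_truth(p)
  s1 <- render_series(gt, p)
  s2 <- render_series(gt, p)
  expect_identical(lapply(s1, `[[`, "pixels"), lapply(s2, `[[`, "pixels"))
  expect_length(s1, 2L)
  for (img in s1) {
    expect_true(min(img$pixels) >= 0 && max(img$pixels) <= 1)
    expect_identical(dim(img$pixels), dim(s1[[1]]$pixels))
  }

  # raising expression never brightens the cell center
  p0 <- sim_params(field_width_um = 80, field_height_um = 80, pixel_size_um = 1,
                   noise_sd = 0, puncta_density = 0, stain_density = 4,
                   classes = class_table(
                     "c" = list(expr = c(GAD67 = 1, PV = 0), count = 0)),
                   misalignment = list(rigid_transform(), rigid_transform()))
  prev <- rep(1, 3)
  for (e in c(0.1, 0.3, 0.6, 1)) {
    gt_e <- manual_gt(p0, 40, 40, 8, "c", list(GAD67 = e, PV = 0))
    ctr <- render_round(gt_e, "GAD67", p0)$pixels[41, 41, ]
    expect_true(all(ctr <= prev + 1e-12))
    prev <- ctr
  }
})

test_that("planted misalignment moves rendered content as specified", {
  p <- sim_params(field_width_um = 150, field_height_um = 150, pixel_size_um = 1,
                  noise_sd = 0, puncta_density = 0,
                  classes = class_table(
                    "c" = list(expr = c(GAD67 = 1, PV = 1), count = 0)),
                  misalignment = list(rigid_transform(),
                                      rigid_transform(10, -6, 0)))
  gt <- manual_gt(p, 75, 75, 8, "c", list(GAD67 = 1, PV = 1))
  s <- render_series(gt, p)
  # round 1 darkest at the planted center, round 2 at the shifted center
  l1 <- luminance(s$GAD67$pixels); l2 <- luminance(s$PV$pixels)
  c1 <- which(l1 == min(l1), arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(c1), c(76, 76), tolerance = 2)
  c2 <- which(l2 == min(l2), arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(c2), c(76 - 6, 76 + 10), tolerance = 2)
})
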