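# Shared fixtures: small seeded simulations built in code.

# two-marker parameter set small enough for unit tests
small_params <- function(..., noise_sd = 0.01) {
  sim_params(
    field_width_um = 300, field_height_um = 300, pixel_size_um = 1,
    classes = class_table(
      "GAD67-only" = list(expr = c(GAD67 = 1, PV = 0), count = 8),
      "GAD67+PV"   = list(expr = c(GAD67 = 1, PV = 1), count = 6)
    ),
    puncta_density = 500, noise_sd = noise_sd, seed = 101L, ...
  )
}

# hand-placed ground truth: full control over positions and expressions
manual_gt <- function(params, x_um, y_um, radius_um, class, expr) {
  n <- length(x_um)
  gt <- data.frame(cell_id = seq_len(n), x_um = x_um, y_um = y_um,
                   radius_um = radius_um, class = class,
                   stringsAsFactors = FALSE)
  for (m in params$markers) gt[[m]] <- expr[[m]]
  transforms <- params$misalignment %||%
    stats::setNames(rep(list(rigid_transform()), length(params$markers)),
                    params$markers)
  names(transforms) <- params$markers
  structure(gt, params = params, transforms = transforms,
            class = c("ihc_ground_truth", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# identity transforms for every round of params
no_misalignment <- function(params) {
  rep(list(rigid_transform()), length(params$markers))
}
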