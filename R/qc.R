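#' Assess stripping completeness from a post-strip control scan
#'
#' Computational analog of the secondary-antibody-only control after
#' stripping: if the previous round were completely removed, a re-developed
#' scan would show no stain. The control image is white-balanced, converted
#' to a signal map, and lightly smoothed at a sub-cellular scale (structures,
#' not single noisy pixels, constitute residual stain); `residual_fraction`
#' is the share of pixels exceeding a threshold derived from the identically
#' smoothed blank reference (median + `qc_k` * MAD). The verdict is `"pass"`
#' iff the fraction stays below `f_max`. The decision is made on pixel
#' fraction rather than mean tint: any visible stained structure should fail
#' the control. When the previous round's signal map is supplied, the
#' correlation between it and the residual map localizes the carryover.
#'
#' @param post_strip [slide_image()] of the post-strip control (with blank
#'   reference); registered to the previous round if a correlation is
#'   requested.
#' @param previous_round_map optional [signal_map()] of the stripped round.
#' @param qc_k MAD multiplier of the residual threshold.
#' @param f_max maximum passing residual pixel fraction.
#' @param smooth_sigma_um smoothing scale of the residual map (micron).
#' @param signal_mode signal extraction mode, as in [extract_signal()].
#' @return object of class `stripping_qc`: `residual_fraction`,
#'   `residual_mean_signal`, `carryover_correlation`, `verdict`,
#'   `threshold`, and the parameters used.
#' @export
assess_stripping <- function(post_strip, previous_round_map = NULL,
                             qc_k = 5, f_max = 0.001, smooth_sigma_um = 2,
                             signal_mode = "inverted_luminance") {
  stopifnot(inherits(post_strip, "slide_image"))
  if (is.null(post_strip$blank_reference))
    stop("stripping QC needs a blank reference for its background estimate")
  wb <- white_balance(post_strip)
  sig <- extract_signal(wb, mode = signal_mode)
  sigma_px <- smooth_sigma_um / post_strip$pixel_size_um
  sm <- gauss_smooth(sig$values, sigma_px)

  blank_img <- slide_image(wb$blank_reference, "blank",
                           pixel_size_um = post_strip$pixel_size_um)
  blank_sig <- gauss_smooth(extract_signal(blank_img, mode = signal_mode)$values,
                            sigma_px)
  bg <- robust_bg(blank_sig)
  tau <- bg$median + qc_k * bg$mad

  above <- sm > tau
  residual_fraction <- mean(above)
  residual_mean <- if (any(above)) mean(sm[above]) else 0

  corr <- NA_real_
  if (!is.null(previous_round_map)) {
    prev <- if (inherits(previous_round_map, "signal_map"))
      previous_round_map$values else previous_round_map
    if (!identical(dim(prev), dim(sm)))
      stop("previous-round map dimensions do not match the control image")
    if (stats::sd(sm) > 0 && stats::sd(prev) > 0)
      corr <- stats::cor(as.numeric(sm), as.numeric(prev))
  }

  structure(list(residual_fraction = residual_fraction,
                 residual_mean_signal = residual_mean,
                 carryover_correlation = corr,
                 verdict = if (residual_fraction < f_max) "pass" else "fail",
                 threshold = tau,
                 parameters = list(qc_k = qc_k, f_max = f_max,
                                   smooth_sigma_um = smooth_sigma_um,
                                   signal_mode = signal_mode)),
            class = "stripping_qc")
}

#' @export
print.stripping_qc <- function(x, ...) {
  cat(sprintf("Stripping QC: %s (residual fraction %.2e, limit %.2e)\n",
              toupper(x$verdict), x$residual_fraction, x$parameters$f_max))
  if (!is.na(x$carryover_correlation))
    cat(sprintf("  residual vs previous round correlation: %.3f\n",
                x$carryover_correlation))
  invisible(x)
}
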