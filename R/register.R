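# Rigid registration of signal maps by windowed phase correlation with a
# coarse-to-fine rotation search. Registration runs on scalar signal maps
# rather than RGB scans: different markers stain different cells, but the
# shared subset of stained structure dominates the correlation peak.

hann2d <- function(nr, nc) {
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  outer(wy, wx)
}

# block-mean downsample by integer factor k (trailing rows/cols cropped)
downsample <- function(m, k) {
  if (k <= 1L) return(m)
  nr <- (nrow(m) %/% k) * k
  nc <- (ncol(m) %/% k) * k
  m <- m[seq_len(nr), seq_len(nc)]
  # average k x k blocks
  m <- matrix(colMeans(matrix(m, nrow = k)), nrow = nr %/% k)
  t(matrix(colMeans(matrix(t(m), nrow = k)), nrow = nc %/% k))
}

# wrap-aware parabolic peak refinement along one axis
parab_refine <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (den >= 0) return(0)
  d <- 0.5 * (ym - yp) / den
  max(min(d, 0.5), -0.5)
}

# Phase correlation of two equally sized matrices. Returns the shift s
# (sx, sy, subpixel) such that b(q) ~= a(q - s), plus the peak height.
phase_corr <- function(fa, b_win) {
  fb <- stats::fft(b_win)
  cross <- fa * Conj(fb)
  mag <- Mod(cross)
  cross <- cross / (mag + 1e-12)
  surf <- Re(stats::fft(cross, inverse = TRUE)) / length(cross)
  nr <- nrow(surf); nc <- ncol(surf)
  k <- which.max(surf)
  i <- (k - 1L) %% nr + 1L
  j <- (k - 1L) %/% nr + 1L
  wrap <- function(idx, n) (idx - 1L) %% n + 1L
  di <- parab_refine(surf[wrap(i - 1L, nr), j], surf[i, j],
                     surf[wrap(i + 1L, nr), j])
  dj <- parab_refine(surf[i, wrap(j - 1L, nc)], surf[i, j],
                     surf[i, wrap(j + 1L, nc)])
  sy <- i - 1L + di; if (sy > nr / 2) sy <- sy - nr
  sx <- j - 1L + dj; if (sx > nc / 2) sx <- sx - nc
  # surf peaks at -s for b(q) = a(q - s)
  list(sx = -sx, sy = -sy, peak = surf[i, j])
}

# peak height of phase correlation after undoing rotation theta on mov
rot_score <- function(fa_win, win, mov, theta) {
  u <- if (theta == 0) mov else warp_matrix(mov, rigid_transform(0, 0, -theta), 0)
  phase_corr(fa_win, u * win)
}

#' Estimate the rigid transform between two signal maps
#'
#' Finds the [rigid_transform()] `t` such that `warp_rigid(reference, t)`
#' matches `moving`; equivalently, `warp_rigid(moving, rt_invert(t))` aligns
#' the moving map onto the reference. Translation comes from windowed phase
#' correlation with parabolic subpixel refinement; rotation from a
#' coarse-to-fine search (on block-averaged maps for speed) maximizing the
#' correlation peak, refined parabolically. Deterministic.
#'
#' @param reference,moving [signal_map()] objects (or plain matrices) of
#'   equal dimensions; both must contain structure (non-constant).
#' @param theta_range half-width of the rotation search in degrees (0 for
#'   translation-only).
#' @param coarse_step,fine_step rotation search steps in degrees.
#' @param search_size target linear size (px) of the downsampled maps used
#'   for the rotation search.
#' @return estimated `rigid_transform` with attribute `peak` (final
#'   correlation peak height).
#' @export
estimate_rigid <- function(reference, moving, theta_range = 3,
                           coarse_step = 0.25, fine_step = 0.05,
                           search_size = 512L) {
  ref <- if (inherits(reference, "signal_map")) reference$values else reference
  mov <- if (inherits(moving, "signal_map")) moving$values else moving
  if (!identical(dim(ref), dim(mov)))
    stop("reference and moving maps must share dimensions")
  if (max(ref) == min(ref) || max(mov) == min(mov))
    stop("no structure to register: constant input map")

  theta <- 0
  if (theta_range > 0) {
    k <- max(1L, floor(min(dim(ref)) / search_size))
    ref_s <- downsample(ref, k); mov_s <- downsample(mov, k)
    win_s <- hann2d(nrow(ref_s), ncol(ref_s))
    fa_s <- stats::fft(ref_s * win_s)
    score <- function(th) rot_score(fa_s, win_s, mov_s, th)$peak
    coarse <- seq(-theta_range, theta_range, by = coarse_step)
    cs <- vapply(coarse, score, numeric(1))
    best <- coarse[which.max(cs)]
    fine <- seq(best - coarse_step, best + coarse_step, by = fine_step)
    fs <- vapply(fine, score, numeric(1))
    b <- which.max(fs)
    theta <- fine[b]
    if (b > 1L && b < length(fine))
      theta <- theta + fine_step * parab_refine(fs[b - 1L], fs[b], fs[b + 1L])
  }

  win <- hann2d(nrow(ref), ncol(ref))
  fa <- stats::fft(ref * win)
  pc <- rot_score(fa, win, mov, theta)
  # the de-rotated moving map equals ref shifted by R(-theta) d
  d <- rot_mat(theta) %*% c(pc$sx, pc$sy)
  structure(rigid_transform(d[1], d[2], theta), peak = pc$peak)
}
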