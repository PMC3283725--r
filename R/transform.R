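# Rigid transforms act on pixel coordinates (x = column, y = row, integer
# pixel centers): p -> R(theta) (p - c) + c + (dx, dy), rotating about the
# raster center c. Warping resamples by inverse mapping with bilinear
# interpolation, so warp(img, t) moves image content forward by t.

#' Rigid transform (translation + rotation about the raster center)
#'
#' @param dx_px,dy_px translation in pixels (x = columns, y = rows).
#' @param theta_deg rotation in degrees about the raster center.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx_px = 0, dy_px = 0, theta_deg = 0) {
  structure(list(dx_px = dx_px, dy_px = dy_px, theta_deg = theta_deg),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: dx = %.4f px, dy = %.4f px, theta = %.4f deg\n",
              x$dx_px, x$dy_px, x$theta_deg))
  invisible(x)
}

rot_mat <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

#' Invert a rigid transform
#'
#' `rt_compose(t, rt_invert(t))` is the identity to machine precision.
#'
#' @param t `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
rt_invert <- function(t) {
  R <- rot_mat(-t$theta_deg)
  d <- -R %*% c(t$dx_px, t$dy_px)
  rigid_transform(d[1], d[2], -t$theta_deg)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `a` first, then `b`.
#'
#' @param a,b `rigid_transform` objects.
#' @return composed `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  # b(a(p)) = Rb Ra (p - c) + c + Rb da + db
  R <- rot_mat(b$theta_deg)
  d <- R %*% c(a$dx_px, a$dy_px) + c(b$dx_px, b$dy_px)
  rigid_transform(d[1], d[2], a$theta_deg + b$theta_deg)
}

#' Apply a rigid transform to point coordinates
#'
#' @param t `rigid_transform`.
#' @param x_px,y_px point coordinates in pixels.
#' @param dim_px raster dimensions `c(rows, cols)` defining the rotation
#'   center.
#' @return list with transformed `x_px`, `y_px`.
#' @export
rt_apply <- function(t, x_px, y_px, dim_px) {
  cx <- (dim_px[2] + 1) / 2
  cy <- (dim_px[1] + 1) / 2
  R <- rot_mat(t$theta_deg)
  xs <- x_px - cx; ys <- y_px - cy
  list(x_px = R[1, 1] * xs + R[1, 2] * ys + cx + t$dx_px,
       y_px = R[2, 1] * xs + R[2, 2] * ys + cy + t$dy_px)
}

# bilinear sample of matrix m at (x, y) vectors; outside -> fill
bilinear_sample <- function(m, x, y, fill) {
  nr <- nrow(m); nc <- ncol(m)
  j0 <- floor(x); i0 <- floor(y)
  fx <- x - j0; fy <- y - i0
  inside <- x >= 1 & x <= nc & y >= 1 & y <= nr
  j0c <- pmin(pmax(j0, 1L), nc); j1c <- pmin(j0c + 1L, nc)
  i0c <- pmin(pmax(i0, 1L), nr); i1c <- pmin(i0c + 1L, nr)
  v <- (1 - fx) * (1 - fy) * m[cbind(i0c, j0c)] +
       fx * (1 - fy) * m[cbind(i0c, j1c)] +
       (1 - fx) * fy * m[cbind(i1c, j0c)] +
       fx * fy * m[cbind(i1c, j1c)]
  v[!inside] <- fill
  v
}

# core warp for a plain matrix
warp_matrix <- function(m, t, fill = 0) {
  if (t$dx_px == 0 && t$dy_px == 0 && t$theta_deg == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  inv <- rt_invert(t)
  grid_x <- rep(seq_len(nc), each = nr)
  grid_y <- rep(seq_len(nr), times = nc)
  src <- rt_apply(inv, grid_x, grid_y, c(nr, nc))
  matrix(bilinear_sample(m, src$x_px, src$y_px, fill), nr, nc)
}

#' Warp an image or signal map by a rigid transform
#'
#' Inverse-mapped resampling with bilinear interpolation. Output dimensions
#' equal input dimensions; pixels sampled from outside the input are filled
#' with white for RGB images and 0 for signal maps (overridable).
#'
#' @param x a `slide_image`, `signal_map`, matrix, or `c(rows, cols, 3)`
#'   array.
#' @param t `rigid_transform` to apply to the content.
#' @param fill fill value for out-of-field samples; default depends on `x`.
#' @return warped object of the same kind.
#' @export
warp_rigid <- function(x, t, fill = NULL) {
  if (inherits(x, "slide_image")) {
    x$pixels <- warp_rigid(x$pixels, t, fill %||% 1)
    return(x)
  }
  if (inherits(x, "signal_map")) {
    x$values <- warp_matrix(x$values, t, fill %||% 0)
    x$frame <- "reference"
    return(x)
  }
  if (is.matrix(x)) return(warp_matrix(x, t, fill %||% 0))
  if (is.array(x) && length(dim(x)) == 3L) {
    f <- rep_len(fill %||% 1, dim(x)[3])
    for (k in seq_len(dim(x)[3])) x[, , k] <- warp_matrix(x[, , k], t, f[k])
    return(x)
  }
  stop("cannot warp object of class ", paste(class(x), collapse = "/"))
}
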