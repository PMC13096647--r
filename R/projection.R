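#' Intensity projections of a volume about the longitudinal axis
#'
#' Collapses a 3D volume to a 2D image by taking the maximum (MIP) or mean
#' (meanIP) voxel value along parallel rays at an angle `theta_deg` about the
#' longitudinal (inferior-superior) axis.  `theta_deg = 0` is the coronal
#' view (rays along the anterior-posterior axis), `theta_deg = 90` the
#' sagittal view (rays along the left-right axis); both are computed exactly.
#' Other angles rotate the transverse plane by `theta_deg` (bilinear
#' interpolation, background fill, plane padded to its diagonal so nothing is
#' clipped) and then project as for 0 degrees.
#'
#' The mean reduction averages over the entire ray, background included, so
#' the pixel value is proportional to the integrated intensity along the ray:
#' thicker tissue projects brighter.  Set `mean_in_mask = TRUE` to average
#' only over non-background voxels instead.
#'
#' @param volume a `volume_grid`.
#' @param theta_deg angle in degrees, in \[-90, 90\].
#' @param reduction `"max"` or `"mean"`.
#' @param fill out-of-grid fill for oblique angles; defaults to the volume's
#'   background value.
#' @param mean_in_mask average only over voxels different from `fill`.
#' @param channel optional channel id recorded on the result.
#' @return A `projection_image`: rows follow the longitudinal axis, columns
#'   the transverse extent.
#' @examples
#' v <- volume_grid(array(1:8, c(2, 2, 2)), c(1, 1, 1), "suv")
#' p <- project(v, 0, "max")
#' dim(p$pixels)  # 2 rows (longitudinal) x 2 columns
#' @export
project <- function(volume, theta_deg, reduction = c("max", "mean"),
                    fill = NULL, mean_in_mask = FALSE, channel = NA_character_) {
  stopifnot(inherits(volume, "volume_grid"))
  reduction <- match.arg(reduction)
  if (!is.finite(theta_deg) || theta_deg < -90 || theta_deg > 90)
    stop("theta_deg must lie in [-90, 90]")
  v <- volume$values
  if (length(v) == 0L)
    stop("empty volume")
  fill <- fill %||% volume$background
  sp <- volume$spacing_mm
  if (theta_deg == 0) {
    px <- reduce_axis(v, axis = 2L, reduction, fill, mean_in_mask)
    col_spacing <- sp[1]
  } else if (abs(theta_deg) == 90) {
    px <- reduce_axis(v, axis = 1L, reduction, fill, mean_in_mask)
    col_spacing <- sp[2]
  } else {
    if (abs(sp[1] - sp[2]) > 1e-8 * max(sp))
      stop("oblique projection requires isotropic in-plane spacing")
    vr <- rotate_transverse(v, theta_deg, fill)
    px <- reduce_axis(vr, axis = 2L, reduction, fill, mean_in_mask)
    col_spacing <- sp[1]
  }
  structure(
    list(pixels = t(px), theta_deg = theta_deg, reduction = reduction,
         channel = channel, pixel_spacing_mm = c(sp[3], col_spacing)),
    class = "projection_image"
  )
}

# Reduce a 3D array along transverse axis 1 or 2; returns (transverse, z).
reduce_axis <- function(v, axis, reduction, fill, mean_in_mask) {
  if (!is.double(v)) storage.mode(v) <- "double"
  op <- if (reduction == "max") 0L else if (mean_in_mask) 2L else 1L
  cpp_reduce_axis(v, as.integer(axis), op, as.numeric(fill))
}

# Rotate the transverse (axis 1-2) plane of a volume by theta degrees about
# its centre, after padding the plane to its diagonal; bilinear interpolation.
rotate_transverse <- function(v, theta_deg, fill) {
  d <- dim(v)
  dg <- ceiling(sqrt(d[1]^2 + d[2]^2))
  padded <- array(fill, c(dg, dg, d[3]))
  off <- floor((dg - d[1:2]) / 2)
  padded[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), ] <- v
  th <- theta_deg * pi / 180
  # rotate about the original volume centre (mapped into padded coords)
  ci <- off[1] + (d[1] + 1) / 2
  cj <- off[2] + (d[2] + 1) / 2
  ij <- expand.grid(i = seq_len(dg), j = seq_len(dg))
  u <- ij$i - ci
  w <- ij$j - cj
  # sample source at R(-theta) applied to output coordinates
  si <- cos(th) * u - sin(th) * w + ci
  sj <- sin(th) * u + cos(th) * w + cj
  bilinear_sample_slices(padded, si, sj, fill)
}

# Sample every z-slice of `vol` (n x n x nz) at fractional in-plane
# coordinates (si, sj) (vectors over the n*n output pixels).
bilinear_sample_slices <- function(vol, si, sj, fill) {
  d <- dim(vol)
  m <- matrix(vol, nrow = d[1] * d[2])
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  inb <- function(ii, jj) ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
  gather <- function(ii, jj) {
    ok <- inb(ii, jj)
    idx <- ifelse(ok, ii + (jj - 1) * d[1], 1)
    g <- m[idx, , drop = FALSE]
    g[!ok, ] <- fill
    g
  }
  out <-
    gather(i0, j0) * ((1 - fi) * (1 - fj)) +
    gather(i0 + 1, j0) * (fi * (1 - fj)) +
    gather(i0, j0 + 1) * ((1 - fi) * fj) +
    gather(i0 + 1, j0 + 1) * (fi * fj)
  array(out, d)
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %s @ %g deg, %d x %d px (channel %s)\n",
              x$reduction, x$theta_deg, nrow(x$pixels), ncol(x$pixels),
              x$channel))
  invisible(x)
}

#' @rdname project
#' @param object a `projection_image`.
#' @param ... ignored.
#' @method autoplot projection_image
#' @export
autoplot.projection_image <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$pixels)),
                           col = seq_len(ncol(object$pixels)))
  df$value <- as.vector(object$pixels)[(df$col - 1L) * nrow(object$pixels) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$reduction) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s projection, theta = %g deg", object$reduction,
                      object$theta_deg),
      x = "transverse (px)", y = "longitudinal (px)")
}
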