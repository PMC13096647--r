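#' Normalize a projection to the unit interval
#'
#' Clips pixel values to the window `[lo, hi]` and maps it linearly onto
#' \[0, 1\].  Fixed global windows (rather than per-subject min-max) keep
#' pixel values comparable across subjects; the defaults used by
#' [assemble_collage()] are \[-1024, 1500\] HU for CT channels and \[0, 30\]
#' for SUV channels.
#'
#' @param projection a `projection_image` (or a plain matrix).
#' @param window numeric `(lo, hi)` with `lo < hi`.
#' @return Same type as the input, values in \[0, 1\].
#' @export
normalize_to_unit <- function(projection, window) {
  lo <- window[1]; hi <- window[2]
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("degenerate window: need lo < hi")
  scale01 <- function(m) (pmin(pmax(m, lo), hi) - lo) / (hi - lo)
  if (inherits(projection, "projection_image")) {
    projection$pixels <- scale01(projection$pixels)
    projection
  } else {
    scale01(projection)
  }
}

#' Pad or crop a 2D image to a fixed canvas
#'
#' Centres the content on an `(H, W)` canvas: any deficit is zero-padded
#' symmetrically (the odd extra pixel goes toward the trailing edge) and any
#' excess is centre-cropped.
#'
#' @param image 2D numeric matrix.
#' @param target integer `(H, W)`.
#' @return `target`-sized matrix.
#' @export
pad_to_canvas <- function(image, target = c(512L, 512L)) {
  target <- as.integer(target)
  if (any(target < 1L)) stop("target canvas must be positive")
  out <- matrix(0, target[1], target[2])
  d <- dim(image)
  take <- pmin(d, target)
  src0 <- floor((d - take) / 2)          # crop offset in the source
  dst0 <- floor((target - take) / 2)     # placement offset on the canvas
  if (all(take > 0))
    out[dst0[1] + seq_len(take[1]), dst0[2] + seq_len(take[2])] <-
      image[src0[1] + seq_len(take[1]), src0[2] + seq_len(take[2])]
  out
}

#' Canvas size implied by an angle list
#'
#' `(512, 512)` for up to two angles, `(512, 1024)` for four: width is
#' `512 * ceiling(n_angles / 2)`.
#'
#' @param angles numeric vector of projection angles (degrees).
#' @return Integer `(H, W)`.
#' @export
collage_canvas <- function(angles) {
  c(512L, 512L * as.integer(ceiling(length(angles) / 2)))
}

#' Assemble the multi-angle, multi-channel collage
#'
#' For every channel of a tissue-wise channel set, projects the volume at
#' each requested angle (MIP for SUV channels, meanIP for CT channels),
#' normalizes to \[0, 1\] with the per-modality window, lays the angles side
#' by side left-to-right in the given order, and pads/crops to the fixed
#' canvas of [collage_canvas()].  The result is the network input: a
#' `H x W x 10` array in [channel_manifest()] order, plus per-angle placement
#' boxes shared by all channels.
#'
#' @param channel_set a `tissue_channel_set` from [apply_masks()].
#' @param angles projection angles in degrees; `c(0, 90)` (the two-view
#'   collage) or `c(0, -45, 45, 90)` (with obliques).
#' @param ct_window,suv_window normalization windows.
#' @param flip_longitudinal place superior at the top row (display
#'   convention); the default keeps array order.
#' @return A `collage`: list with `channels` (H x W x 10 array), `angles`,
#'   `manifest`, `boxes` (tibble of per-angle placement boxes), `windows`.
#' @export
assemble_collage <- function(channel_set, angles = c(0, 90),
                             ct_window = c(-1024, 1500),
                             suv_window = c(0, 30),
                             flip_longitudinal = FALSE) {
  if (!inherits(channel_set, "tissue_channel_set"))
    stop("channel_set must be a tissue_channel_set")
  manifest <- channel_manifest()
  missing <- setdiff(manifest, names(channel_set))
  if (length(missing))
    stop("missing channels: ", paste(missing, collapse = ", "))
  if (!length(angles) %in% c(1L, 2L, 4L) || anyNA(angles) ||
      any(angles < -90 | angles > 90) || anyDuplicated(angles))
    stop("unsupported angle list; use c(0, 90), c(0, -45, 45, 90), ",
         "a single angle, or a permutation of one of these")
  canvas <- collage_canvas(angles)

  per_channel <- function(name) {
    vol <- channel_set[[name]]
    is_suv <- grepl("^suv", name)
    red <- if (is_suv) "max" else "mean"
    win <- if (is_suv) suv_window else ct_window
    mats <- lapply(angles, function(th) {
      p <- project(vol, th, red, channel = name)
      m <- normalize_to_unit(p$pixels, win)
      if (flip_longitudinal) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
      m
    })
    widths <- vapply(mats, ncol, integer(1))
    strip <- do.call(cbind, mats)
    list(canvas = pad_to_canvas(strip, canvas), widths = widths,
         strip_dim = dim(strip))
  }

  first <- per_channel(manifest[1])
  channels <- array(0, c(canvas, 10L))
  channels[, , 1] <- first$canvas
  for (k in 2:10) channels[, , k] <- per_channel(manifest[k])$canvas

  widths <- first$widths
  strip_d <- first$strip_dim
  take <- pmin(strip_d, canvas)
  src0 <- floor((strip_d - take) / 2)
  dst0 <- floor((canvas - take) / 2)
  col_off <- cumsum(c(0L, widths[-length(widths)]))
  # strip column range of angle a, mapped through crop/placement to the canvas
  boxes <- tibble::tibble(
    angle = angles,
    row0 = dst0[1] + 1L,
    row1 = dst0[1] + take[1],
    col0 = pmax(col_off + 1L - src0[2], 1L) + dst0[2],
    col1 = pmin(col_off + widths - src0[2], take[2]) + dst0[2]
  )
  structure(
    list(channels = channels, angles = angles, manifest = manifest,
         boxes = boxes, windows = list(ct = ct_window, suv = suv_window),
         flip_longitudinal = flip_longitudinal),
    class = "collage"
  )
}

#' @export
print.collage <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<collage> %d x %d canvas, %d channels, angles [%s]\n",
              d[1], d[2], d[3], paste(x$angles, collapse = ", ")))
  invisible(x)
}

#' Block-average a collage to a coarser grid
#'
#' Downscales each channel by integer block averaging, for compact network
#' inputs at test scale.  The canvas must be divisible by `factor`.
#'
#' @param collage a `collage`.
#' @param factor integer downscale factor.
#' @return The collage with `channels` of size `(H/factor, W/factor, C)`;
#'   placement boxes are rescaled.
#' @export
shrink_collage <- function(collage, factor) {
  stopifnot(inherits(collage, "collage"))
  d <- dim(collage$channels)
  if (any(d[1:2] %% factor != 0))
    stop("canvas not divisible by factor ", factor)
  h <- d[1] %/% factor; w <- d[2] %/% factor
  x <- collage$channels
  dim(x) <- c(factor, h, factor, w, d[3])
  collage$channels <- colMeans(aperm(x, c(1, 3, 2, 4, 5)), dims = 2)
  collage$orig_boxes <- collage$boxes
  collage$boxes <- dplyr::mutate(
    collage$boxes,
    row0 = pmax(1L, as.integer(ceiling(.data$row0 / factor))),
    row1 = as.integer(ceiling(.data$row1 / factor)),
    col0 = pmax(1L, as.integer(ceiling(.data$col0 / factor))),
    col1 = as.integer(ceiling(.data$col1 / factor)))
  collage$shrink_factor <- factor
  collage
}

#' @rdname assemble_collage
#' @param object a `collage`.
#' @param ... ignored.
#' @method autoplot collage
#' @export
autoplot.collage <- function(object, ...) {
  d <- dim(object$channels)
  df <- tidyr::expand_grid(channel = factor(object$manifest,
                                            levels = object$manifest),
                           col = seq_len(d[2]), row = seq_len(d[1]))
  df$value <- as.vector(aperm(object$channels, c(1, 2, 3)))[
    (as.integer(df$channel) - 1L) * d[1] * d[2] + (df$col - 1L) * d[1] + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel, ncol = 2) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}
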