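#' Grad-CAM saliency for a collage prediction
#'
#' Gradient-weighted class activation mapping against the feature maps of
#' the network's first convolutional layer.  The output scalar (regression
#' value or classification logit) is backpropagated to the first layer's
#' post-activation feature maps `A^k`; each map is weighted by the spatial
#' mean `alpha_k` of its gradient, the weighted sum is rectified, bilinearly
#' upsampled to the collage canvas, and max-normalized to \[0, 1\] (unless
#' the maximum is zero).
#'
#' @param model a `tw_model`.
#' @param collage a `collage` (or plain `(H, W, C)` array) matching the
#'   model's input channels.
#' @param subject_id optional id recorded on the map.
#' @return A `saliency_map`: `heatmap` (canvas-sized, non-negative),
#'   `feature_maps` (`A^k`), `weights` (`alpha_k`), `boxes` (the collage's
#'   placement boxes, if available), `task`, `subject_id`.
#' @export
grad_cam <- function(model, collage, subject_id = NA_character_) {
  stopifnot(inherits(model, "tw_model"))
  ch <- if (inherits(collage, "collage")) collage$channels else collage
  d <- dim(ch)
  if (length(d) != 3L || d[3] != model$spec$input_channels)
    stop("collage must be (H, W, C) with C = ", model$spec$input_channels)
  if (model$layers[[1]]$type != "conv")
    stop("first layer is not a convolution")
  x <- array(ch, c(d, 1L))
  fw <- cnn_forward(model$layers, x, train = FALSE, keep_out = 1L)
  bw <- cnn_backward(model$layers, fw$caches, gout = 1, grad_at = 1L)
  dA <- dim(fw$kept)[1:3]               # (oh, ow, K)
  A <- array(fw$kept, dA)
  G <- array(bw$layer_grad, dA)
  k <- dA[3]
  alpha <- vapply(seq_len(k), function(j) mean(G[, , j]), numeric(1))
  cam <- array(0, dim(A)[1:2])
  for (j in seq_len(k)) cam <- cam + alpha[j] * A[, , j]
  cam <- pmax(cam, 0)
  heat <- upsample_bilinear(cam, d[1], d[2])
  heat <- pmax(heat, 0)
  mx <- max(heat)
  if (mx > 0) heat <- heat / mx
  structure(
    list(heatmap = heat, feature_maps = A, weights = alpha,
         boxes = if (inherits(collage, "collage")) collage$boxes else NULL,
         task = model$spec$task, subject_id = subject_id),
    class = "saliency_map"
  )
}

# Bilinear resize of a matrix to (H, W) with centre-aligned sampling.
upsample_bilinear <- function(m, H, W) {
  d <- dim(m)
  gi <- ((seq_len(H) - 0.5) * d[1] / H) + 0.5
  gj <- ((seq_len(W) - 0.5) * d[2] / W) + 0.5
  ci <- pmin(pmax(gi, 1), d[1]); cj <- pmin(pmax(gj, 1), d[2])
  i0 <- pmax(pmin(floor(ci), d[1] - 1L), 1L)
  j0 <- pmax(pmin(floor(cj), d[2] - 1L), 1L)
  if (d[1] == 1L) i0 <- rep(1L, H)
  if (d[2] == 1L) j0 <- rep(1L, W)
  fi <- ci - i0; fj <- cj - j0
  i1 <- pmin(i0 + 1L, d[1]); j1 <- pmin(j0 + 1L, d[2])
  m[i0, j0, drop = FALSE] * outer(1 - fi, 1 - fj) +
    m[i1, j0, drop = FALSE] * outer(fi, 1 - fj) +
    m[i0, j1, drop = FALSE] * outer(1 - fi, fj) +
    m[i1, j1, drop = FALSE] * outer(fi, fj)
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %d x %d canvas, %d feature maps (subject %s)\n",
              nrow(x$heatmap), ncol(x$heatmap), length(x$weights),
              x$subject_id))
  invisible(x)
}

#' @rdname grad_cam
#' @param object a `saliency_map`.
#' @param ... ignored.
#' @method autoplot saliency_map
#' @export
autoplot.saliency_map <- function(object, ...) {
  df <- tidyr::expand_grid(col = seq_len(ncol(object$heatmap)),
                           row = seq_len(nrow(object$heatmap)))
  df$value <- as.vector(object$heatmap)[(df$col - 1L) * nrow(object$heatmap) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "saliency") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Aggregate individual saliency maps by sex on the shared canvas
#'
#' Pixelwise mean of the (per-map max-normalized) saliency maps within each
#' sex group.  Aggregation happens directly in the shared padded canvas
#' space, which is appropriate when subjects occupy a common geometry (as the
#' size-normalized synthetic cohort does); no deformable registration is
#' performed.  Groups are additionally split per projection-angle placement
#' box when boxes are available.
#'
#' @param maps list of `saliency_map`s on identical canvases.
#' @param meta tibble with `subject_id` and `sex` columns covering the maps.
#' @return A `cohort_saliency`: named list (one element per sex present)
#'   with `mean_map`, `n`, and `per_angle` crops.
#' @export
aggregate_cohort_saliency <- function(maps, meta) {
  stopifnot(length(maps) >= 1)
  d <- dim(maps[[1]]$heatmap)
  ids <- vapply(maps, function(m) m$subject_id, character(1))
  sex <- meta$sex[match(ids, meta$subject_id)]
  if (anyNA(sex)) stop("some maps have no metadata row")
  groups <- list()
  for (s in c("female", "male")) {
    sel <- which(sex == s)
    if (length(sel) == 0L) {
      warning("no subjects with sex = ", s, "; group omitted")
      next
    }
    acc <- matrix(0, d[1], d[2])
    for (i in sel) {
      if (!identical(dim(maps[[i]]$heatmap), d))
        stop("saliency maps are on different canvases")
      acc <- acc + maps[[i]]$heatmap
    }
    mean_map <- acc / length(sel)
    boxes <- maps[[sel[1]]]$boxes
    per_angle <- NULL
    if (!is.null(boxes)) {
      per_angle <- purrr::pmap(boxes, function(angle, row0, row1, col0, col1) {
        list(angle = angle, map = mean_map[row0:row1, col0:col1, drop = FALSE])
      })
    }
    groups[[s]] <- list(mean_map = mean_map, n = length(sel),
                        per_angle = per_angle)
  }
  structure(groups, class = "cohort_saliency")
}

#' @export
print.cohort_saliency <- function(x, ...) {
  for (s in names(x))
    cat(sprintf("<cohort_saliency> %s: n = %d, %d x %d canvas\n",
                s, x[[s]]$n, nrow(x[[s]]$mean_map), ncol(x[[s]]$mean_map)))
  invisible(x)
}

#' Map a volume-space bounding box onto the collage canvas
#'
#' Converts an axis-aligned voxel-index box (for example a lesion's bounding
#' box in the annotation mask) into canvas pixel coordinates for the
#' coronal (0 degree) or sagittal (90 degree) placement box of a collage.
#' Useful for checking that saliency concentrates on a known structure.
#'
#' @param collage a `collage` (possibly shrunk via [shrink_collage()]).
#' @param angle 0 or 90.
#' @param x_range,y_range,z_range integer voxel index ranges `c(lo, hi)` of
#'   the box in the source volume.
#' @return Tibble with `row0`, `row1`, `col0`, `col1` canvas coordinates.
#' @export
project_box <- function(collage, angle, x_range, y_range, z_range) {
  stopifnot(inherits(collage, "collage"), angle %in% c(0, 90))
  if (isTRUE(collage$flip_longitudinal))
    stop("project_box requires flip_longitudinal = FALSE collages")
  full <- collage$orig_boxes %||% collage$boxes
  box <- dplyr::filter(full, .data$angle == !!angle)
  if (nrow(box) != 1L) stop("angle ", angle, " not present in the collage")
  f <- collage$shrink_factor %||% 1L
  trans <- if (angle == 0) x_range else y_range
  rows <- z_range
  d <- dim(collage$channels)
  tibble::tibble(
    row0 = max(1L, as.integer(ceiling((box$row0 - 1L + rows[1]) / f))),
    row1 = min(d[1], as.integer(ceiling((box$row0 - 1L + rows[2]) / f))),
    col0 = max(1L, as.integer(ceiling((box$col0 - 1L + trans[1]) / f))),
    col1 = min(d[2], as.integer(ceiling((box$col0 - 1L + trans[2]) / f))))
}
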