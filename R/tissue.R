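#' Partition a CT volume into tissue masks by Hounsfield-unit thresholding
#'
#' Classifies every voxel of a CT volume into one of four tissue
#' compartments by its Hounsfield unit `i`:
#' \describe{
#'   \item{bone}{`i >= 200`}
#'   \item{lean}{`-29 <= i <= 150`}
#'   \item{adipose}{`-190 <= i <= -30`}
#'   \item{air}{`i < -190`}
#' }
#' The thresholds are applied literally, so the HU intervals `(150, 200)` and
#' `(-30, -29)` belong to no compartment; such "gap" voxels stay unmasked.
#' With `strict = FALSE` the number of gap voxels is reported as a message
#' instead of silently ignored.
#'
#' @param ct `volume_grid` of kind `"hu"`.
#' @param strict if `FALSE`, message the count of voxels falling in the
#'   unassigned HU gaps.
#' @return A `tissue_mask_set`: list of four binary `volume_grid`s
#'   (`bone`, `lean`, `adipose`, `air`) on the CT grid.
#' @examples
#' ct <- volume_grid(array(c(300, 0, -100, -500, 175, 1, 1, 1), c(2, 2, 2)),
#'                   c(1, 1, 1), "hu")
#' m <- tissue_masks(ct)
#' m$bone$values[1, 1, 1]  # 1: HU 300 is bone
#' @export
tissue_masks <- function(ct, strict = TRUE) {
  stopifnot_kind(ct, "hu")
  hu <- ct$values
  mk <- function(m) {
    storage.mode(m) <- "integer"
    new_volume_grid(m, ct$spacing_mm, "label")
  }
  bone    <- hu >= 200
  lean    <- hu >= -29 & hu <= 150
  adipose <- hu >= -190 & hu <= -30
  air     <- hu < -190
  if (!strict) {
    n_gap <- sum(!(bone | lean | adipose | air))
    if (n_gap > 0)
      message(n_gap, " voxel(s) fall in the unassigned HU gaps (150, 200) and (-30, -29)")
  }
  structure(
    list(bone = mk(bone), lean = mk(lean), adipose = mk(adipose), air = mk(air)),
    class = "tissue_mask_set"
  )
}

#' @export
print.tissue_mask_set <- function(x, ...) {
  n <- vapply(x, function(m) sum(m$values), numeric(1))
  cat("<tissue_mask_set>", paste(names(x), n, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Fixed channel order of the tissue-wise channel set
#'
#' @return Character vector of the ten channel names in canonical order.
#' @export
channel_manifest <- function() {
  c("ct_orig", "suv_orig", "ct_bone", "suv_bone", "ct_lean", "suv_lean",
    "ct_adipose", "suv_adipose", "ct_air", "suv_air")
}

#' Build the ten tissue-wise CT and SUV volumes
#'
#' Multiplies the CT and SUV volumes by each binary tissue mask, yielding the
#' ten channels `{original, bone, lean, adipose, air} x {CT, SUV}` in the
#' canonical order of [channel_manifest()].  Masked-out voxels are 0 in every
#' tissue channel (mask-by-multiplication), including the CT channels, whose
#' background therefore differs from raw CT air; the masked channels carry
#' `background = 0` so later rotation/resampling fills consistently.
#'
#' @param ct `volume_grid` of kind `"hu"`.
#' @param suv `volume_grid` of kind `"suv"`.
#' @param masks a `tissue_mask_set` from [tissue_masks()].
#' @return A `tissue_channel_set`: named list of ten `volume_grid`s.
#' @export
apply_masks <- function(ct, suv, masks) {
  stopifnot_kind(ct, "hu")
  stopifnot_kind(suv, "suv")
  stopifnot(inherits(masks, "tissue_mask_set"))
  d <- dim(ct$values)
  if (!identical(d, dim(suv$values)))
    stop("CT and SUV volume shapes differ")
  if (!isTRUE(all.equal(ct$spacing_mm, suv$spacing_mm)))
    stop("CT and SUV voxel spacings differ")
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]$values), d))
      stop("mask '", nm, "' shape differs from the CT grid")
  }
  ch <- list(ct_orig = ct, suv_orig = suv)
  for (nm in c("bone", "lean", "adipose", "air")) {
    m <- masks[[nm]]$values
    ch[[paste0("ct_", nm)]] <-
      new_volume_grid(ct$values * m, ct$spacing_mm, "hu", background = 0)
    ch[[paste0("suv_", nm)]] <-
      new_volume_grid(suv$values * m, suv$spacing_mm, "suv", background = 0)
  }
  structure(ch[channel_manifest()], class = "tissue_channel_set")
}

#' @export
print.tissue_channel_set <- function(x, ...) {
  cat("<tissue_channel_set> 10 channels:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
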