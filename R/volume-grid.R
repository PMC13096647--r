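#' 3D scalar volumes with voxel spacing and a declared value kind
#'
#' A `volume_grid` is the package's basic image container: a 3D array of
#' voxel values together with its voxel spacing in mm and a declaration of
#' what the values mean (`"hu"` for CT Hounsfield units, `"activity_bq_ml"`
#' for PET activity concentration, `"suv"` for standardized uptake values, or
#' `"label"` for binary annotation masks).  The axis convention is fixed:
#' axis 1 runs left-right, axis 2 anterior-posterior, axis 3
#' inferior-superior (the longitudinal axis).
#'
#' Each kind carries a background value used to fill out-of-grid samples when
#' resampling or rotating: -1024 HU for CT, 0 otherwise.  Volumes derived by
#' masking (see [apply_masks()]) override the background to 0.
#'
#' @param values 3D numeric array.
#' @param spacing_mm numeric length-3, strictly positive, voxel spacing in mm
#'   along the three axes.
#' @param value_kind one of `"hu"`, `"activity_bq_ml"`, `"suv"`, `"label"`.
#' @param background optional scalar overriding the kind's default background.
#' @return A `volume_grid` object.
#' @examples
#' v <- volume_grid(array(0, c(4, 4, 4)), c(1, 1, 1), "hu")
#' dim(v$values)
#' @export
volume_grid <- function(values, spacing_mm, value_kind, background = NULL) {
  value_kind <- match.arg(value_kind, c("hu", "activity_bq_ml", "suv", "label"))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3D volume, got ", length(dim(values)) %||% 1L, " dimensions")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be three strictly positive values")
  if (value_kind == "label") {
    u <- unique(as.vector(values))
    if (!all(u %in% c(0, 1)))
      stop("label volumes may contain only 0 and 1")
    storage.mode(values) <- "integer"
  }
  if (is.null(background))
    background <- default_background(value_kind)
  structure(
    list(values = values, spacing_mm = spacing_mm, value_kind = value_kind,
         background = background),
    class = "volume_grid"
  )
}

# Internal fast path: build a volume_grid from already-validated pieces.
new_volume_grid <- function(values, spacing_mm, value_kind, background = NULL) {
  structure(
    list(values = values, spacing_mm = spacing_mm, value_kind = value_kind,
         background = background %||% default_background(value_kind)),
    class = "volume_grid"
  )
}

default_background <- function(value_kind) {
  if (value_kind == "hu") -1024 else 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %s, %d x %d x %d voxels @ (%.3g, %.3g, %.3g) mm\n",
    x$value_kind, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
    x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

stopifnot_kind <- function(volume, kind) {
  if (!inherits(volume, "volume_grid"))
    stop("expected a volume_grid")
  if (!volume$value_kind %in% kind)
    stop("expected a volume of kind ", paste(kind, collapse = "/"),
         ", got ", volume$value_kind)
  invisible(volume)
}

#' Read a 3D volume from a NIfTI file
#'
#' Reads voxel data and spacing from a `.nii`/`.nii.gz` file.  The value kind
#' is declared by the caller (NIfTI carries no such semantics).
#'
#' @param path path to an existing NIfTI file.
#' @param value_kind declared value kind, see [volume_grid()].
#' @return A `volume_grid`.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, value_kind = "hu") {
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # drop NIfTI header attributes
  if (length(dim(arr)) != 3L)
    stop("expected 3D volume in ", path, ", got ", length(dim(arr)), "D")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in NIfTI header of ", path)
  volume_grid(arr, sp, value_kind)
}

#' Write a volume to a NIfTI file
#'
#' @param volume a `volume_grid`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_grid"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Resample a volume to a target voxel spacing
#'
#' Resamples onto a new axis-aligned grid covering the same physical extent
#' (to within one voxel), with voxel-centre sampling.  Intensities (HU,
#' activity, SUV) are interpolated trilinearly; labels use nearest-neighbour.
#' Samples falling outside the source grid take the volume's background value.
#'
#' The pipeline's common grid follows whole-body PET reconstruction
#' conventions: 2.04 x 2.04 x 3 mm.
#'
#' @param volume a `volume_grid`.
#' @param target_spacing_mm numeric length-3, strictly positive.
#' @return A `volume_grid` at the target spacing.
#' @export
resample <- function(volume, target_spacing_mm = c(2.04, 2.04, 3)) {
  stopifnot(inherits(volume, "volume_grid"))
  tsp <- as.numeric(target_spacing_mm)
  if (length(tsp) != 3L || any(!is.finite(tsp)) || any(tsp <= 0))
    stop("target spacing must be three strictly positive values")
  src <- volume$values
  d <- dim(src)
  sp <- volume$spacing_mm
  if (isTRUE(all.equal(sp, tsp)))
    return(volume)
  nout <- pmax(1L, as.integer(round(d * sp / tsp)))
  # physical coordinate of output voxel centre i: (i - 0.5) * tsp
  # source index space (1-based centres): s = phys / sp + 0.5
  gi <- lapply(1:3, function(a) ((seq_len(nout[a]) - 0.5) * tsp[a]) / sp[a] + 0.5)
  if (volume$value_kind == "label") {
    idx <- lapply(1:3, function(a) pmin(pmax(round(gi[[a]]), 1L), d[a]))
    out <- src[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    # nearest-neighbour centres more than half a source voxel outside -> background
    outside <- lapply(1:3, function(a) gi[[a]] < 0.5 | gi[[a]] > d[a] + 0.5)
    if (any(unlist(outside))) {
      out[outside[[1]], , ] <- volume$background
      out[, outside[[2]], ] <- volume$background
      out[, , outside[[3]]] <- volume$background
    }
    dim(out) <- nout
    return(volume_grid(out, tsp, "label", background = volume$background))
  }
  out <- trilinear_sample(src, gi[[1]], gi[[2]], gi[[3]], fill = volume$background)
  volume_grid(out, tsp, volume$value_kind, background = volume$background)
}

# Trilinear interpolation of `src` at the tensor grid gx x gy x gz of
# (1-based, fractional) source indices; coordinates outside
# [0.5, n + 0.5] are filled, and the boundary half-voxel clamps to the edge
# value (constant extrapolation within half a voxel, as for cell-centred data).
trilinear_sample <- function(src, gx, gy, gz, fill = 0) {
  d <- dim(src)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  cx <- pmin(pmax(gx, 1), d[1]); cy <- pmin(pmax(gy, 1), d[2]); cz <- pmin(pmax(gz, 1), d[3])
  i0 <- pmin(floor(cx), d[1] - 1L); i0 <- pmax(i0, 1L)
  j0 <- pmin(floor(cy), d[2] - 1L); j0 <- pmax(j0, 1L)
  k0 <- pmin(floor(cz), d[3] - 1L); k0 <- pmax(k0, 1L)
  if (d[1] == 1L) i0 <- rep(1L, nx)
  if (d[2] == 1L) j0 <- rep(1L, ny)
  if (d[3] == 1L) k0 <- rep(1L, nz)
  fx <- cx - i0; fy <- cy - j0; fz <- cz - k0
  i1 <- pmin(i0 + 1L, d[1]); j1 <- pmin(j0 + 1L, d[2]); k1 <- pmin(k0 + 1L, d[3])

  gather <- function(ii, jj, kk) {
    idx <- outer(outer(ii, (jj - 1L) * d[1], `+`), (kk - 1L) * d[1] * d[2], `+`)
    array(src[idx], c(nx, ny, nz))
  }
  wx1 <- array(fx, c(nx, ny, nz))
  wy1 <- aperm(array(fy, c(ny, nx, nz)), c(2, 1, 3))
  wz1 <- aperm(array(fz, c(nz, nx, ny)), c(2, 3, 1))
  out <-
    gather(i0, j0, k0) * (1 - wx1) * (1 - wy1) * (1 - wz1) +
    gather(i1, j0, k0) * wx1 * (1 - wy1) * (1 - wz1) +
    gather(i0, j1, k0) * (1 - wx1) * wy1 * (1 - wz1) +
    gather(i1, j1, k0) * wx1 * wy1 * (1 - wz1) +
    gather(i0, j0, k1) * (1 - wx1) * (1 - wy1) * wz1 +
    gather(i1, j0, k1) * wx1 * (1 - wy1) * wz1 +
    gather(i0, j1, k1) * (1 - wx1) * wy1 * wz1 +
    gather(i1, j1, k1) * wx1 * wy1 * wz1
  ox <- gx < 0.5 | gx > d[1] + 0.5
  oy <- gy < 0.5 | gy > d[2] + 0.5
  oz <- gz < 0.5 | gz > d[3] + 0.5
  if (any(ox)) out[ox, , ] <- fill
  if (any(oy)) out[, oy, ] <- fill
  if (any(oz)) out[, , oz] <- fill
  out
}

#' Convert PET activity concentration to SUV
#'
#' Body-weight-normalized standardized uptake value:
#' `SUV = activity[Bq/ml] * body_weight[g] / injected_dose[Bq]`.
#' The stored activity is assumed decay-corrected to injection time; no decay
#' term is applied.
#'
#' @param pet `volume_grid` of kind `"activity_bq_ml"`.
#' @param meta one-row subject metadata (see [subject_meta()]) or any list
#'   with `body_weight_kg` and `injected_dose_mbq`.
#' @return A `volume_grid` of kind `"suv"`.
#' @examples
#' pet <- volume_grid(array(5000, c(2, 2, 2)), c(2, 2, 2), "activity_bq_ml")
#' m <- subject_meta("s1", body_weight_kg = 70, injected_dose_mbq = 350,
#'                   age_years = 60, sex = "female", diagnosis = "negative")
#' compute_suv(pet, m)$values[1]  # 1.0
#' @export
compute_suv <- function(pet, meta) {
  stopifnot_kind(pet, "activity_bq_ml")
  w <- meta$body_weight_kg
  d <- meta$injected_dose_mbq
  if (is.null(w) || !is.finite(w) || w <= 0)
    stop("body weight must be strictly positive for SUV conversion")
  if (is.null(d) || !is.finite(d) || d <= 0)
    stop("injected dose must be strictly positive for SUV conversion")
  suv <- pet$values * (w * 1000) / (d * 1e6)
  volume_grid(suv, pet$spacing_mm, "suv")
}

#' Per-subject metadata records
#'
#' One row per subject, as a tibble: identifiers, SUV-conversion quantities
#' (body weight, injected dose), and demographics.  Diagnosis status is
#' derived as `"cancer"` for any diagnosis other than `"negative"`.
#'
#' @param subject_id character.
#' @param body_weight_kg positive real (kg).
#' @param injected_dose_mbq positive real (MBq).
#' @param age_years real in \[0, 120\].
#' @param sex one of `"female"`, `"male"`, `"unknown"`.
#' @param diagnosis one of `"negative"`, `"lymphoma"`, `"lung_cancer"`,
#'   `"melanoma"`.
#' @return A one-row tibble with a derived `diagnosis_status` column.
#' @export
subject_meta <- function(subject_id, body_weight_kg, injected_dose_mbq,
                         age_years, sex, diagnosis) {
  sex <- match.arg(sex, c("female", "male", "unknown"))
  diagnosis <- match.arg(diagnosis,
                         c("negative", "lymphoma", "lung_cancer", "melanoma"))
  if (!is.finite(age_years) || age_years < 0 || age_years > 120)
    stop("age_years must lie in [0, 120]")
  tibble::tibble(
    subject_id = as.character(subject_id),
    body_weight_kg = as.numeric(body_weight_kg),
    injected_dose_mbq = as.numeric(injected_dose_mbq),
    age_years = as.numeric(age_years),
    sex = sex,
    diagnosis = diagnosis,
    diagnosis_status = ifelse(diagnosis == "negative", "no_cancer", "cancer")
  )
}
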