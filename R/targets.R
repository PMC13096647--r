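#' Total metabolic tumor volume of an annotation mask
#'
#' TMTV in millilitres: the number of labeled voxels times the voxel volume.
#'
#' @param label binary `volume_grid` of kind `"label"`.
#' @return TMTV in ml.
#' @examples
#' m <- array(0L, c(10, 10, 10)); m[1:10, 1:10, 1:10] <- 1L
#' tmtv(volume_grid(m, c(1, 1, 1), "label"))  # 1 ml
#' @export
tmtv <- function(label) {
  stopifnot_kind(label, "label")
  sum(label$values) * prod(label$spacing_mm) / 1000
}

#' Number of lesions in an annotation mask
#'
#' Counts connected components of the binary mask under the chosen 3D
#' connectivity.  26-connectivity (faces, edges and corners) is the default,
#' the usual choice for PET lesion blobs.
#'
#' @param label binary `volume_grid` of kind `"label"`.
#' @param connectivity 6, 18 or 26.
#' @return Integer lesion count.
#' @export
lesion_count <- function(label, connectivity = 26) {
  stopifnot_kind(label, "label")
  lab <- cpp_label_components(label$values, as.integer(connectivity))
  attr(lab, "ncomp")
}

#' Label the connected components of a binary mask
#'
#' @inheritParams lesion_count
#' @return A `volume_grid` of integer component labels (0 = background) with
#'   an `ncomp` attribute; not a binary label volume.
#' @export
label_components <- function(label, connectivity = 26) {
  stopifnot_kind(label, "label")
  lab <- cpp_label_components(label$values, as.integer(connectivity))
  out <- label
  out$values <- lab
  out$value_kind <- "label_components"
  class(out) <- c("component_labels", "volume_grid")
  out
}

#' Derive the prediction-target table for a cohort
#'
#' Combines annotation-derived quantities (TMTV, lesion count) with the
#' metadata demographics into one row per subject: the ground truth for the
#' regression (TMTV, lesion count, age) and classification (sex, diagnosis
#' status) tasks.
#'
#' @param labels named list of binary `volume_grid`s, one per subject.
#' @param meta tibble of subject metadata rows ([subject_meta()]).
#' @param connectivity lesion-counting connectivity.
#' @return A tibble: `subject_id`, `tmtv_ml`, `lesion_count`, `age_years`,
#'   `sex`, `diagnosis`, `diagnosis_status`.
#' @export
derive_targets <- function(labels, meta, connectivity = 26) {
  stopifnot(all(meta$subject_id %in% names(labels)))
  per <- purrr::map(meta$subject_id, function(id) {
    lab <- labels[[id]]
    tibble::tibble(subject_id = id, tmtv_ml = tmtv(lab),
                   lesion_count = lesion_count(lab, connectivity))
  })
  dplyr::left_join(dplyr::bind_rows(per), meta, by = "subject_id")
}
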