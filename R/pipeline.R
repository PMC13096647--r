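#' Preprocess one subject: common grid and SUV conversion
#'
#' Resamples the CT and PET volumes to the common voxel grid and converts
#' PET activity to body-weight-normalized SUV.
#'
#' @param ct `volume_grid` of kind `"hu"`.
#' @param pet `volume_grid` of kind `"activity_bq_ml"`.
#' @param meta one-row subject metadata.
#' @param target_spacing_mm common grid spacing.
#' @return List with resampled `ct` and `suv` volumes.
#' @export
preprocess_subject <- function(ct, pet, meta,
                               target_spacing_mm = c(2.04, 2.04, 3)) {
  ct_r <- resample(ct, target_spacing_mm)
  suv <- resample(compute_suv(pet, meta), target_spacing_mm)
  list(ct = ct_r, suv = suv)
}

#' Build the tissue-wise collage for one subject
#'
#' Convenience wrapper: tissue masks, channel set, collage.
#'
#' @param ct,suv volumes on a common grid.
#' @param angles projection angles.
#' @param shrink optional integer block-average factor applied to the canvas.
#' @param ... passed to [assemble_collage()].
#' @return A `collage`.
#' @export
subject_collage <- function(ct, suv, angles = c(0, 90), shrink = NULL, ...) {
  ch <- apply_masks(ct, suv, tissue_masks(ct))
  cl <- assemble_collage(ch, angles = angles, ...)
  if (!is.null(shrink)) cl <- shrink_collage(cl, shrink)
  cl
}

#' Generate a phantom cohort ready for network training
#'
#' Runs the full front half of the pipeline on synthetic subjects: phantom
#' generation, SUV conversion, tissue decomposition, projection, collage
#' assembly and optional block-averaging — returning the stacked network
#' input together with the ground-truth target table.  Volumes are processed
#' one at a time so memory stays bounded.
#'
#' @param n number of subjects.
#' @param seed cohort seed.
#' @param angles projection angles for the collage.
#' @param shrink block-average factor for the network input (e.g. 8 maps the
#'   512-wide canvas to 64); `NULL` keeps the full canvas.
#' @param params a [phantom_params()].
#' @param mix diagnosis proportions, see [generate_cohort()].
#' @return List with `x` (`(H, W, 10, n)` array), `targets` (tibble of
#'   per-subject ground truth incl. `tmtv_ml`, `lesion_count`, demographics),
#'   `template` (the first subject's collage, carrying placement boxes), and
#'   `lesions` (per-subject lesion tables).
#' @export
phantom_study <- function(n, seed = 1, angles = c(0, 90), shrink = 8,
                          params = phantom_params(),
                          mix = c(negative = 0.5, lymphoma = 0.17,
                                  lung_cancer = 0.17, melanoma = 0.16)) {
  stopifnot(n >= 1)
  counts <- diff(round(cumsum(c(0, mix)) * n))
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  plan <- with_seed(seed, list(diag = sample(rep(names(mix), counts)),
                               seeds = sample.int(2147483646L, n)))
  x <- NULL
  targets <- vector("list", n)
  lesions <- vector("list", n)
  template <- NULL
  for (i in seq_len(n)) {
    p <- params
    p$diagnosis <- plan$diag[i]
    ph <- generate_phantom(p, seed = plan$seeds[i],
                           subject_id = sprintf("phantom_%03d", i))
    suv <- compute_suv(ph$pet, ph$meta)
    cl <- subject_collage(ph$ct, suv, angles = angles, shrink = shrink)
    if (is.null(x)) {
      d <- dim(cl$channels)
      x <- array(0, c(d, n))
      template <- cl
    }
    x[, , , i] <- cl$channels
    targets[[i]] <- dplyr::bind_cols(
      tibble::tibble(tmtv_ml = tmtv(ph$label),
                     lesion_count = lesion_count(ph$label)),
      ph$meta)
    lesions[[i]] <- ph$lesions
  }
  targets <- dplyr::relocate(dplyr::bind_rows(targets), "subject_id")
  list(x = x, targets = targets, template = template, lesions = lesions)
}
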