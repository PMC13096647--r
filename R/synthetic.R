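#' Parameters of the synthetic whole-body phantom
#'
#' Controls the geometry, tissue intensity models, lesion burden and
#' demographics model of the phantom generator.  Defaults emulate a
#' head-to-mid-thigh FDG-PET/CT examination on the pipeline's common grid:
#' 96 x 96 x 160 voxels at 2.04 x 2.04 x 3 mm, with tissue Hounsfield units
#' drawn per compartment (lean 40 +- 15, adipose -100 +- 20, cortical bone
#' ~ (900 - 2.5 (age - 10)) +- 100, lung -800 +- 50, exterior air
#' -1000 +- 30), an FDG background of roughly SUV 1 in lean tissue with an
#' avid brain, and spherical lesions of uptake SUV 5-15.
#'
#' Age drives the subcutaneous adipose thickness and the mean bone HU
#' monotonically, so age regression has recoverable signal; sex drives the
#' shoulder/hip geometry and adiposity.  Injected dose is drawn from a
#' clipped normal mirroring typical oncologic PET protocols
#' (mean 315 MBq, range 150-432).
#'
#' @param shape integer grid dimensions.
#' @param spacing_mm voxel spacing.
#' @param noise_scale scales all voxel noise standard deviations; 0 yields a
#'   noiseless phantom.
#' @param lesion_uptake_suv range of per-lesion SUV.
#' @param tmtv_meanlog,tmtv_sdlog,tmtv_range lognormal total lesion volume
#'   (ml) and its truncation range.
#' @param lesion_count_mu,lesion_count_size negative-binomial lesion count
#'   (shifted by 1), capped at `lesion_count_max`.
#' @param lesion_count_max cap on the per-subject lesion count.
#' @param min_lesion_ml smallest per-lesion volume.
#' @param age,sex,diagnosis,weight_kg,dose_mbq,lesion_volumes_ml optional
#'   fixed values overriding the demographic / lesion draws.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(shape = c(96L, 96L, 160L),
                           spacing_mm = c(2.04, 2.04, 3),
                           noise_scale = 1,
                           lesion_uptake_suv = c(5, 15),
                           tmtv_meanlog = log(25), tmtv_sdlog = 1,
                           tmtv_range = c(2, 300),
                           lesion_count_mu = 3, lesion_count_size = 1.5,
                           lesion_count_max = 10,
                           min_lesion_ml = 1.5,
                           age = NULL, sex = NULL, diagnosis = NULL,
                           weight_kg = NULL, dose_mbq = NULL,
                           lesion_volumes_ml = NULL) {
  structure(as.list(environment()), class = "phantom_params")
}

# Compartment codes used throughout the generator.
PH_EXTERIOR <- 0L; PH_LEAN <- 1L; PH_ADIPOSE <- 2L; PH_BONE <- 3L
PH_LUNG <- 4L; PH_BRAIN <- 5L

phantom_hu_model <- function(age) {
  list(mean = c(-1000, 40, -100, 900 - 2.5 * (age - 10), -800, 40),
       sd = c(30, 15, 20, 100, 50, 15))
}

phantom_suv_model <- function() {
  list(mean = c(0.02, 1.0, 0.3, 0.5, 0.3, 4.0), sd = 0.1)
}

# Body landmark geometry in voxel units, scaled to the grid shape.
# Proportions are anchored to the default 96 x 96 x 160 grid.
phantom_geometry <- function(shape, sex, age) {
  nx <- shape[1]; nz <- shape[3]
  male <- sex == "male"
  sx <- nx / 96; sz <- nz / 160
  list(
    cx = (shape[1] + 1) / 2, cy = (shape[2] + 1) / 2,
    shoulder_rx = (if (male) 40 else 34) * sx,
    hip_rx = (if (male) 31 else 37) * sx,
    ry_torso = (if (male) 23 else 22) * sx,
    t_adip = ((if (male) 2.0 else 3.0) + 3.0 * (age - 11) / 84) * sx,
    leg_sep = (if (male) 14 else 15) * sx,
    r_leg = 10.5 * sx, r_femur = 3.5 * sx,
    r_head = 15 * sx, head_cz = 147 * sz,
    z_leg = 54 * sz, z_torso = 128 * sz, z_neck = 136 * sz,
    spine_dy = 10 * sx, r_spine = 4 * sx, r_neck = 8 * sx,
    lung_dx = 16 * sx, lung_dy = -2 * sx, lung_cz = 112 * sz,
    lung_ax = 10 * sx, lung_ay = 12 * sx, lung_az = 14 * sz
  )
}

# Build the compartment-coded phantom body for one subject.
phantom_compartments <- function(shape, age, sex) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  g <- phantom_geometry(shape, sex, age)
  X <- matrix(seq_len(nx), nx, ny)
  Y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  tis <- array(PH_EXTERIOR, shape)
  spine_y <- g$cy + g$spine_dy
  for (z in seq_len(nz)) {
    code <- matrix(PH_EXTERIOR, nx, ny)
    if (z <= g$z_leg) {
      taper <- 0.85 + 0.15 * z / g$z_leg
      for (sgn in c(-1, 1)) {
        lx <- g$cx + sgn * g$leg_sep
        rr <- sqrt((X - lx)^2 + (Y - g$cy)^2) / (g$r_leg * taper)
        code[rr <= 1] <- PH_LEAN
        code[rr <= 1 & rr > 1 - g$t_adip / (g$r_leg * taper)] <- PH_ADIPOSE
        code[sqrt((X - lx)^2 + (Y - g$cy)^2) <= g$r_femur] <- PH_BONE  # femur
      }
    } else if (z <= g$z_torso) {
      a <- (z - g$z_leg) / (g$z_torso - g$z_leg)
      rx <- g$hip_rx + (g$shoulder_rx - g$hip_rx) * a
      rho <- sqrt(((X - g$cx) / rx)^2 + ((Y - g$cy) / g$ry_torso)^2)
      code[rho <= 1] <- PH_LEAN
      code[rho <= 1 & rho > 1 - g$t_adip / min(rx, g$ry_torso)] <- PH_ADIPOSE
      # lungs: two ellipsoids in the upper torso
      for (sgn in c(-1, 1)) {
        lung <- ((X - (g$cx + sgn * g$lung_dx)) / g$lung_ax)^2 +
          ((Y - (g$cy + g$lung_dy)) / g$lung_ay)^2 +
          ((z - g$lung_cz) / g$lung_az)^2
        code[lung <= 1 & code == PH_LEAN] <- PH_LUNG
      }
      code[sqrt((X - g$cx)^2 + (Y - spine_y)^2) <= g$r_spine] <- PH_BONE  # spine
    } else if (z <= g$z_neck) {
      rr <- sqrt((X - g$cx)^2 + (Y - g$cy)^2)
      code[rr <= g$r_neck] <- PH_LEAN
      code[sqrt((X - g$cx)^2 + (Y - spine_y + 6)^2) <= 0.75 * g$r_spine] <- PH_BONE
    } else {
      rz_head <- 15 * nz / 160
      dz2n <- ((z - g$head_cz) / rz_head)^2
      if (dz2n < 1) {
        rho <- sqrt(((X - g$cx)^2 + (Y - g$cy)^2) / g$r_head^2 + dz2n)
        code[rho <= 1 & rho > 0.93] <- PH_ADIPOSE
        code[rho <= 0.93 & rho > 0.80] <- PH_BONE   # skull
        code[rho <= 0.80] <- PH_BRAIN
      }
    }
    tis[, , z] <- code
  }
  tis
}

# Draw per-lesion volumes: lognormal total split by gamma weights.
draw_lesion_volumes <- function(p) {
  if (!is.null(p$lesion_volumes_ml)) return(p$lesion_volumes_ml)
  v_tot <- min(max(exp(rnorm(1, p$tmtv_meanlog, p$tmtv_sdlog)), p$tmtv_range[1]),
               p$tmtv_range[2])
  n <- min(1 + rnbinom(1, mu = p$lesion_count_mu, size = p$lesion_count_size),
           p$lesion_count_max)
  n <- max(1L, min(n, floor(v_tot / p$min_lesion_ml)))
  w <- rgamma(n, shape = 2)
  v <- v_tot * w / sum(w)
  v <- pmax(v, p$min_lesion_ml)
  v <- v * (v_tot / sum(v))
  # single very large spheres do not fit the torso; cap per-lesion volume
  pmin(pmax(v, p$min_lesion_ml), 100)
}

# Place spherical lesions inside the lean torso; error if one cannot fit.
place_lesions <- function(vols_ml, shape, spacing, sex, age = 50) {
  g <- phantom_geometry(shape, sex, age)
  cx <- g$cx; cy <- g$cy
  placed <- list()
  for (i in seq_along(vols_ml)) {
    r_mm <- (3 * vols_ml[i] * 1000 / (4 * pi))^(1 / 3)
    rz_vox <- r_mm / spacing[3]
    ok <- FALSE
    for (try in seq_len(400)) {
      z0 <- runif(1, g$z_leg + 2 + rz_vox + 1, g$z_torso - 1 - rz_vox - 1)
      u <- runif(1, -0.6, 0.6); v <- runif(1, -0.5, 0.5)
      x0 <- cx + u * g$hip_rx
      y0 <- cy + v * g$ry_torso
      # keep the centre clear of the spine and the lungs
      if (sqrt((x0 - cx)^2 + (y0 - (cy + g$spine_dy))^2) < 1.75 * g$r_spine) next
      in_lung <- FALSE
      for (sgn in c(-1, 1)) {
        if (((x0 - (cx + sgn * g$lung_dx)) / g$lung_ax)^2 +
            ((y0 - (cy + g$lung_dy)) / g$lung_ay)^2 +
            ((z0 - g$lung_cz) / g$lung_az)^2 < 1.2) in_lung <- TRUE
      }
      if (in_lung) next
      clash <- FALSE
      for (pl in placed) {
        d_mm <- sqrt(((x0 - pl$x) * spacing[1])^2 + ((y0 - pl$y) * spacing[2])^2 +
                     ((z0 - pl$z) * spacing[3])^2)
        if (d_mm < r_mm + pl$r_mm + 2 * max(spacing)) { clash <- TRUE; break }
      }
      if (clash) next
      placed[[i]] <- list(x = x0, y = y0, z = z0, r_mm = r_mm, vol_ml = vols_ml[i])
      ok <- TRUE
      break
    }
    if (!ok)
      stop("lesion ", i, " (radius ", round(r_mm, 1),
           " mm) cannot be placed inside the phantom body")
  }
  placed
}

rasterize_lesions <- function(placed, shape, spacing) {
  lab <- array(0L, shape)
  if (length(placed) == 0L) return(lab)
  for (pl in placed) {
    rx <- ceiling(pl$r_mm / spacing[1]); ry <- ceiling(pl$r_mm / spacing[2])
    rz <- ceiling(pl$r_mm / spacing[3])
    xs <- max(1L, floor(pl$x - rx)):min(shape[1], ceiling(pl$x + rx))
    ys <- max(1L, floor(pl$y - ry)):min(shape[2], ceiling(pl$y + ry))
    zs <- max(1L, floor(pl$z - rz)):min(shape[3], ceiling(pl$z + rz))
    dx2 <- ((xs - pl$x) * spacing[1])^2
    dy2 <- ((ys - pl$y) * spacing[2])^2
    dz2 <- ((zs - pl$z) * spacing[3])^2
    sph <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= pl$r_mm^2
    lab[xs, ys, zs][sph] <- 1L
  }
  lab
}

#' Generate one synthetic FDG-PET/CT phantom
#'
#' Builds a paired CT volume (HU), PET activity volume (Bq/ml), binary
#' lesion mask and metadata row for one synthetic subject.  Deterministic
#' given `seed`.  Cancer-negative subjects get an empty mask; lesions appear
#' as FDG-avid spheres in both the PET volume and the mask.
#'
#' @param params a [phantom_params()].
#' @param seed RNG seed.
#' @param subject_id id recorded in the metadata.
#' @return List with `ct`, `pet`, `label` (`volume_grid`s), `meta` (one-row
#'   tibble), `compartments` (integer array of generator tissue codes:
#'   0 exterior, 1 lean, 2 adipose, 3 bone, 4 lung, 5 brain), and `lesions`
#'   (tibble of placed lesion centres/radii).
#' @export
generate_phantom <- function(params = phantom_params(), seed = 1,
                             subject_id = "phantom_01") {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(seed, {
    sex <- params$sex %||% sample(c("female", "male"), 1)
    age <- params$age %||% min(max(rnorm(1, 60, 15), 11), 95)
    diagnosis <- params$diagnosis %||%
      sample(c("negative", "lymphoma", "lung_cancer", "melanoma"), 1,
             prob = c(0.5, 0.17, 0.17, 0.16))
    weight <- params$weight_kg %||%
      min(max(rnorm(1, if (sex == "male") 85 else 70, 12), 45), 130)
    dose <- params$dose_mbq %||% min(max(rnorm(1, 315, 40), 150), 432)
    meta <- subject_meta(subject_id, weight, dose, age, sex, diagnosis)

    shape <- params$shape; spacing <- params$spacing_mm
    tis <- phantom_compartments(shape, age, sex)
    hu_model <- phantom_hu_model(age)
    ns <- params$noise_scale
    nvox <- prod(shape)
    ct_vals <- hu_model$mean[tis + 1L] +
      (if (ns > 0) rnorm(nvox, 0, ns * hu_model$sd[tis + 1L]) else 0)
    dim(ct_vals) <- shape
    suv_model <- phantom_suv_model()
    suv_vals <- suv_model$mean[tis + 1L] +
      (if (ns > 0) rnorm(nvox, 0, ns * suv_model$sd) else 0)
    dim(suv_vals) <- shape

    lesions <- tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                              r_mm = numeric(), vol_ml = numeric(),
                              uptake_suv = numeric())
    lab <- array(0L, shape)
    if (meta$diagnosis_status == "cancer") {
      vols <- draw_lesion_volumes(params)
      placed <- place_lesions(vols, shape, spacing, sex, age)
      lab <- rasterize_lesions(placed, shape, spacing)
      uptakes <- runif(length(placed), params$lesion_uptake_suv[1],
                       params$lesion_uptake_suv[2])
      for (i in seq_along(placed)) {
        pl <- placed[[i]]
        rx <- ceiling(pl$r_mm / spacing[1]); ry <- ceiling(pl$r_mm / spacing[2])
        rz <- ceiling(pl$r_mm / spacing[3])
        xs <- max(1L, floor(pl$x - rx)):min(shape[1], ceiling(pl$x + rx))
        ys <- max(1L, floor(pl$y - ry)):min(shape[2], ceiling(pl$y + ry))
        zs <- max(1L, floor(pl$z - rz)):min(shape[3], ceiling(pl$z + rz))
        sph <- outer(outer(((xs - pl$x) * spacing[1])^2,
                           ((ys - pl$y) * spacing[2])^2, `+`),
                     ((zs - pl$z) * spacing[3])^2, `+`) <= pl$r_mm^2
        block <- suv_vals[xs, ys, zs]
        block[sph] <- uptakes[i] +
          (if (ns > 0) rnorm(sum(sph), 0, ns * suv_model$sd) else 0)
        suv_vals[xs, ys, zs] <- block
      }
      lesions <- dplyr::bind_rows(purrr::imap(placed, function(pl, i) {
        tibble::tibble(x = pl$x, y = pl$y, z = pl$z, r_mm = pl$r_mm,
                       vol_ml = pl$vol_ml, uptake_suv = uptakes[i])
      }))
    }
    suv_vals <- pmax(suv_vals, 0)
    activity <- suv_vals * (dose * 1e6) / (weight * 1000)
    list(
      ct = volume_grid(ct_vals, spacing, "hu"),
      pet = volume_grid(activity, spacing, "activity_bq_ml"),
      label = volume_grid(lab, spacing, "label"),
      meta = meta,
      compartments = tis,
      lesions = lesions
    )
  })
}

#' Generate a synthetic cohort
#'
#' Draws `n` subjects with a fixed diagnosis mix (matched within rounding),
#' generating the paired volumes with per-subject seeds derived from `seed`.
#' With `dir` set, the cohort is written to disk in the layout the pipeline
#' consumes: per-subject NIfTI volumes (`<id>_ct.nii.gz`, `<id>_pet.nii.gz`,
#' `<id>_label.nii.gz`), a `metadata.csv` table and a `manifest.json`
#' recording seeds and parameters for exact regeneration.
#'
#' @param n number of subjects.
#' @param mix named diagnosis proportions summing to 1.
#' @param seed RNG seed.
#' @param params a [phantom_params()].
#' @param dir output directory, or `NULL` to keep the cohort in memory.
#' @return With `dir = NULL`, list with `phantoms` (list of
#'   [generate_phantom()] results) and `meta` (cohort tibble); otherwise the
#'   manifest (invisibly) after writing.
#' @export
generate_cohort <- function(n, mix = c(negative = 0.5, lymphoma = 0.17,
                                       lung_cancer = 0.17, melanoma = 0.16),
                            seed = 1, params = phantom_params(), dir = NULL) {
  stopifnot(n >= 1)
  if (abs(sum(mix) - 1) > 1e-6 || any(mix < 0))
    stop("diagnosis proportions must be non-negative and sum to 1")
  counts <- diff(round(cumsum(c(0, mix)) * n))
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  diag_vec <- rep(names(mix), counts)
  out <- with_seed(seed, {
    diag_vec <- sample(diag_vec)
    sub_seeds <- sample.int(2147483646L, n)
    list(diag_vec = diag_vec, sub_seeds = sub_seeds)
  })
  phantoms <- vector("list", n)
  metas <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params
    p$diagnosis <- out$diag_vec[i]
    ph <- generate_phantom(p, seed = out$sub_seeds[i],
                           subject_id = sprintf("phantom_%03d", i))
    phantoms[[i]] <- ph
    metas[[i]] <- ph$meta
  }
  meta <- dplyr::bind_rows(metas)
  if (is.null(dir))
    return(list(phantoms = phantoms, meta = meta))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ph in phantoms) {
    id <- ph$meta$subject_id
    write_volume(ph$ct, file.path(dir, paste0(id, "_ct.nii.gz")))
    write_volume(ph$pet, file.path(dir, paste0(id, "_pet.nii.gz")))
    write_volume(ph$label, file.path(dir, paste0(id, "_label.nii.gz")))
  }
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  manifest <- list(n = n, seed = seed, subject_seeds = out$sub_seeds,
                   diagnosis = out$diag_vec,
                   shape = params$shape, spacing_mm = params$spacing_mm,
                   noise_scale = params$noise_scale)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
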