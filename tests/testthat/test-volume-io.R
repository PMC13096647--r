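test_that("NIfTI round trip preserves values and spacing", {
  v <- volume_grid(array(rnorm(4 * 4 * 4), c(4, 4, 4)), c(1.5, 2, 3), "hu")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  r <- read_volume(path, "hu")
  expect_equal(r$values, v$values, tolerance = 0)
  expect_equal(r$spacing_mm, v$spacing_mm)

  z <- volume_grid(array(0, c(4, 4, 4)), c(1, 1, 1), "hu")
  pz <- tempfile(fileext = ".nii.gz")
  write_volume(z, pz)
  rz <- read_volume(pz, "hu")
  expect_true(all(rz$values == 0))
  expect_equal(rz$spacing_mm, c(1, 1, 1))
})

test_that("volume reading rejects missing files and non-3D images", {
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  img2d <- RNifti::asNifti(matrix(0, 5, 5))
  p2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img2d, p2)
  expect_error(read_volume(p2), "3D")
})

test_that("volume_grid validates spacing, dimensionality and labels", {
  expect_error(volume_grid(array(0, c(2, 2, 2)), c(1, -1, 1), "hu"), "positive")
  expect_error(volume_grid(matrix(0, 2, 2), c(1, 1, 1), "hu"), "3D")
  expect_error(volume_grid(array(2, c(2, 2, 2)), c(1, 1, 1), "label"), "0 and 1")
})

test_that("resampling preserves constants and is the identity at equal spacing", {
  v <- volume_grid(array(7, c(10, 10, 10)), c(1, 1, 1), "suv")
  r <- resample(v, c(2.04, 2.04, 3))
  expect_equal(r$spacing_mm, c(2.04, 2.04, 3))
  expect_true(all(abs(r$values - 7) < 1e-12))
  # physical extent preserved within one voxel
  expect_true(all(abs(dim(r$values) * r$spacing_mm - c(10, 10, 10)) <=
                    r$spacing_mm))
  same <- resample(v, c(1, 1, 1))
  expect_identical(same$values, v$values)
  expect_error(resample(v, c(0, 1, 1)), "positive")
})

test_that("resampling a linear ramp matches the analytic values at voxel centres", {
  d <- c(4, 4, 40)
  ramp <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)  # f(z) = z (index)
  v <- volume_grid(ramp, c(1, 1, 1), "suv")
  r <- resample(v, c(1, 1, 0.8))
  # output voxel centre k sits at physical z = (k - 0.5) * 0.8, i.e. source
  # index (k - 0.5) * 0.8 + 0.5; the ramp value there is that index
  expected <- (seq_len(dim(r$values)[3]) - 0.5) * 0.8 + 0.5
  interior <- expected >= 1 & expected <= d[3]
  got <- r$values[2, 2, ]
  expect_true(max(abs(got[interior] - expected[interior])) < 1e-6)
})

test_that("label volumes resample by nearest neighbour and stay binary", {
  lab <- array(0L, c(8, 8, 8)); lab[3:6, 3:6, 3:6] <- 1L
  v <- volume_grid(lab, c(1, 1, 1), "label")
  r <- resample(v, c(2, 2, 2))
  expect_true(all(r$values %in% c(0L, 1L)))
  expect_equal(dim(r$values), c(4L, 4L, 4L))
})

test_that("SUV conversion follows the body-weight formula and is linear", {
  pet <- volume_grid(array(5000, c(3, 3, 3)), c(2, 2, 2), "activity_bq_ml")
  m <- subject_meta("s", 70, 350, 60, "male", "negative")
  suv <- compute_suv(pet, m)
  expect_equal(suv$values[1, 1, 1], 1.0)  # 5000 * 70000 / 3.5e8
  expect_equal(suv$value_kind, "suv")

  zero <- volume_grid(array(0, c(3, 3, 3)), c(2, 2, 2), "activity_bq_ml")
  expect_true(all(compute_suv(zero, m)$values == 0))

  pet2 <- volume_grid(2 * pet$values, c(2, 2, 2), "activity_bq_ml")
  expect_equal(compute_suv(pet2, m)$values, 2 * suv$values)

  bad <- m; bad$injected_dose_mbq <- 0
  expect_error(compute_suv(pet, bad), "dose")
  bad2 <- m; bad2$body_weight_kg <- -1
  expect_error(compute_suv(pet, bad2), "weight")
})

test_that("subject metadata derives diagnosis status and validates fields", {
  m <- subject_meta("a", 80, 300, 45, "female", "melanoma")
  expect_equal(m$diagnosis_status, "cancer")
  expect_equal(subject_meta("b", 80, 300, 45, "male", "negative")$diagnosis_status,
               "no_cancer")
  expect_error(subject_meta("c", 80, 300, 130, "male", "negative"), "age")
  expect_error(subject_meta("d", 80, 300, 45, "other", "negative"))
})
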