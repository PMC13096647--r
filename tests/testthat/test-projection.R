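test_that("coronal and sagittal projections match the brute-force oracle", {
  v <- volume_grid(array(1:8, c(2, 2, 2)), c(1, 1, 1), "suv")
  p <- project(v, 0, "max")
  expect_equal(p$pixels, brute_project(v$values, 2, "max"))

  set.seed(99)
  for (i in 1:20) {
    d <- c(sample(2:7, 1), sample(2:7, 1), sample(2:6, 1))
    vv <- random_volume(d)
    for (red in c("max", "mean")) {
      expect_equal(project(vv, 0, red)$pixels,
                   brute_project(vv$values, 2, red), tolerance = 1e-12)
      expect_equal(project(vv, 90, red)$pixels,
                   brute_project(vv$values, 1, red), tolerance = 1e-12)
    }
  }
})

test_that("projection image geometry follows the contract", {
  v <- random_volume(c(5, 7, 9), seed = 3)
  p0 <- project(v, 0, "max")
  expect_equal(nrow(p0$pixels), 9)   # rows = longitudinal size
  expect_equal(ncol(p0$pixels), 5)
  p90 <- project(v, 90, "mean")
  expect_equal(dim(p90$pixels), c(9L, 7L))
  expect_error(project(v, 120, "max"), "theta")
  expect_error(project(volume_grid(array(1, c(1, 1, 1)), c(1, 1, 1),
                                   "suv")[c("values", "spacing_mm")],
                       0, "max"))
})

test_that("mean projection of a constant volume is constant", {
  v <- volume_grid(array(4.5, c(6, 6, 6)), c(1, 1, 1), "suv")
  for (th in c(0, 90))
    expect_true(all(abs(project(v, th, "mean")$pixels - 4.5) < 1e-12))
})

test_that("max projection is monotone in the voxel values", {
  set.seed(11)
  a <- random_volume(c(5, 5, 5))
  b <- a
  b$values <- a$values + array(runif(125, 0, 2), dim(a$values))
  for (th in c(0, 90))
    expect_true(all(project(a, th, "max")$pixels <=
                      project(b, th, "max")$pixels))
})

test_that("sagittal projection equals coronal projection of the axis-swapped volume", {
  v <- random_volume(c(6, 9, 4), seed = 21)
  sw <- volume_grid(aperm(v$values, c(2, 1, 3)), c(1, 1, 1), "suv")
  for (red in c("max", "mean"))
    expect_identical(project(v, 90, red)$pixels, project(sw, 0, red)$pixels)
})

test_that("oblique projection of a rotationally symmetric phantom matches coronal", {
  # smooth Gaussian cylinder: projections at any angle agree up to interpolation
  n <- 41
  ctr <- (n + 1) / 2
  r2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  slab <- exp(-r2 / (2 * 8^2))
  v <- volume_grid(array(rep(slab, 10), c(n, n, 10)), c(1, 1, 3), "suv",
                   background = 0)
  # max: pixel values agree directly on the coronal field of view
  p0 <- project(v, 0, "max")$pixels
  p45 <- project(v, 45, "max")$pixels
  off <- floor((ncol(p45) - ncol(p0)) / 2)
  expect_lt(max(abs(p45[, off + seq_len(ncol(p0))] - p0)),
            0.02 * diff(range(p0)))
  # mean: full-ray means are integrals divided by the ray length, which the
  # diagonal padding enlarges; compare the rotation-invariant ray integrals
  m0 <- project(v, 0, "mean")$pixels * n
  m45 <- project(v, 45, "mean")$pixels * nrow(tissuewise:::rotate_transverse(
    v$values, 45, 0))
  expect_lt(max(abs(m45[, off + seq_len(ncol(m0))] - m0)),
            0.02 * diff(range(m0)))
})

test_that("oblique projections require isotropic in-plane spacing", {
  v <- volume_grid(array(1, c(4, 4, 4)), c(1, 2, 1), "suv")
  expect_error(project(v, 45, "max"), "isotropic")
  expect_silent(project(v, 90, "max"))
})

test_that("in-mask mean averages only over non-background voxels", {
  vals <- array(0, c(2, 4, 1))
  vals[1, , 1] <- c(2, 0, 0, 6)   # two masked-in voxels along the ray
  v <- volume_grid(vals, c(1, 1, 1), "suv", background = 0)
  full <- project(v, 0, "mean")$pixels
  inm <- project(v, 0, "mean", mean_in_mask = TRUE)$pixels
  expect_equal(full[1, 1], 2)   # (2 + 0 + 0 + 6) / 4
  expect_equal(inm[1, 1], 4)    # (2 + 6) / 2
  expect_equal(inm[1, 2], 0)    # empty ray falls back to the background
})
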