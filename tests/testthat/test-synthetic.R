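test_that("phantom generation is bit-identical given the seed", {
  p <- tiny_phantom_params()
  a <- generate_phantom(p, seed = 5)
  b <- generate_phantom(p, seed = 5)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$pet$values, b$pet$values)
  expect_identical(a$label$values, b$label$values)
  expect_identical(a$meta, b$meta)
  c2 <- generate_phantom(p, seed = 6)
  expect_false(identical(a$ct$values, c2$ct$values))
})

test_that("requested lesions appear as that many connected components", {
  p <- tiny_phantom_params(diagnosis = "lymphoma",
                           lesion_volumes_ml = c(12, 8, 5))
  ph <- generate_phantom(p, seed = 9)
  expect_equal(lesion_count(ph$label, 26), 3)
  expect_equal(nrow(ph$lesions), 3)
  # lesions are FDG-avid: SUV inside the mask well above background
  suv <- compute_suv(ph$pet, ph$meta)
  expect_gt(min(suv$values[ph$label$values == 1]), 3)
})

test_that("negative subjects carry empty masks", {
  ph <- generate_phantom(tiny_phantom_params(diagnosis = "negative"), seed = 2)
  expect_equal(sum(ph$label$values), 0)
  expect_equal(tmtv(ph$label), 0)
})

test_that("rasterized lesion volume matches the request within voxelization error", {
  p <- tiny_phantom_params(diagnosis = "melanoma", lesion_volumes_ml = c(30, 20))
  ph <- generate_phantom(p, seed = 13)
  expect_lt(abs(tmtv(ph$label) - 50) / 50, 0.10)
})

test_that("oversized lesion requests fail with an informative error", {
  p <- tiny_phantom_params(diagnosis = "lymphoma",
                           lesion_volumes_ml = rep(90, 8))
  expect_error(generate_phantom(p, seed = 1), "cannot be placed")
})

test_that("tissue HU draws fall in their threshold interval with prob >= 0.95", {
  ph <- generate_phantom(phantom_params(age = 50), seed = 21)
  tis <- ph$compartments
  hu <- ph$ct$values
  frac_in <- function(sel, lo, hi) mean(hu[sel] >= lo & hu[sel] <= hi)
  expect_gte(frac_in(tis == 3, 200, Inf), 0.95)           # bone
  expect_gte(frac_in(tis %in% c(1, 5), -29, 150), 0.95)   # lean (+brain)
  expect_gte(frac_in(tis == 2, -190, -30), 0.95)          # adipose
  expect_gte(frac_in(tis %in% c(0, 4), -Inf, -190.001), 0.95)  # air + lung
})

test_that("threshold masks recover the noiseless phantom compartments", {
  ph <- generate_phantom(phantom_params(noise_scale = 0, age = 60), seed = 3)
  masks <- tissue_masks(ph$ct)
  tis <- ph$compartments
  jac <- function(a, b) sum(a & b) / sum(a | b)
  expect_gte(jac(masks$bone$values == 1, tis == 3), 0.95)
  expect_gte(jac(masks$lean$values == 1, tis %in% c(1, 5)), 0.95)
  expect_gte(jac(masks$adipose$values == 1, tis == 2), 0.95)
  expect_gte(jac(masks$air$values == 1, tis %in% c(0, 4)), 0.95)
})

test_that("cohort generation matches the diagnosis mix and writes a full layout", {
  dir <- file.path(tempdir(), "cohort_test")
  on.exit(unlink(dir, recursive = TRUE))
  generate_cohort(8, mix = c(negative = 0.5, lymphoma = 0.5, lung_cancer = 0,
                             melanoma = 0),
                  seed = 4, params = tiny_phantom_params(), dir = dir)
  meta <- read.csv(file.path(dir, "metadata.csv"))
  expect_equal(nrow(meta), 8)
  expect_equal(sum(meta$diagnosis == "negative"), 4)
  for (id in meta$subject_id) {
    expect_true(file.exists(file.path(dir, paste0(id, "_ct.nii.gz"))))
    expect_true(file.exists(file.path(dir, paste0(id, "_pet.nii.gz"))))
    expect_true(file.exists(file.path(dir, paste0(id, "_label.nii.gz"))))
  }
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n, 8)
  # negative subjects have empty masks on disk
  neg <- meta$subject_id[meta$diagnosis == "negative"][1]
  lab <- read_volume(file.path(dir, paste0(neg, "_label.nii.gz")), "label")
  expect_equal(sum(lab$values), 0)
  expect_error(generate_cohort(4, mix = c(negative = 0.8, lymphoma = 0.8,
                                          lung_cancer = 0, melanoma = 0)),
               "sum to 1")
})

test_that("cohort lesion volumes are positively skewed under the lognormal spec", {
  p <- tiny_phantom_params()
  tm <- sapply(1:40, function(i) {
    pp <- p; pp$diagnosis <- "lymphoma"
    tmtv(generate_phantom(pp, seed = 1000 + i)$label)
  })
  skew <- mean(((tm - mean(tm)) / sd(tm))^3)
  expect_gt(skew, 0)
  expect_true(all(tm >= p$tmtv_range[1] * 0.8))
  expect_true(all(tm <= p$tmtv_range[2] * 1.2))
})

test_that("age and sex leave monotone, recoverable traces in the phantom", {
  young <- generate_phantom(phantom_params(noise_scale = 0, age = 20,
                                           sex = "male"), seed = 1)
  old <- generate_phantom(phantom_params(noise_scale = 0, age = 90,
                                         sex = "male"), seed = 1)
  # adipose fraction grows with age; mean bone HU falls
  expect_gt(sum(old$compartments == 2), sum(young$compartments == 2))
  expect_lt(mean(old$ct$values[old$compartments == 3]),
            mean(young$ct$values[young$compartments == 3]))
  f <- generate_phantom(phantom_params(noise_scale = 0, age = 50,
                                       sex = "female"), seed = 1)
  m <- generate_phantom(phantom_params(noise_scale = 0, age = 50,
                                       sex = "male"), seed = 1)
  body_f <- f$compartments > 0; body_m <- m$compartments > 0
  expect_gt(mean(f$compartments[body_f] == 2), mean(m$compartments[body_m] == 2))
})
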