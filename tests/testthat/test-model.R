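# Small random inputs where the target is a simple function of the image, so
# the tiny network can learn/memorize quickly.
toy_task <- function(n, d = c(16, 16, 2), seed = 1, task = "regression") {
  set.seed(seed)
  x <- array(runif(prod(d) * n), c(d, n))
  bright <- apply(x[, , 1, , drop = FALSE], 4, mean)
  if (task == "regression") {
    y <- 100 * bright   # target: mean brightness of channel 1, scaled
  } else {
    y <- as.integer(bright > median(bright))
  }
  list(x = x, y = y)
}

test_that("stratified folds partition the cohort and preserve proportions", {
  records <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:100),
    sex = rep(c("female", "male"), each = 50),
    diagnosis = rep(rep(c("negative", "lymphoma"), each = 25), 2))
  plan <- make_folds(records, k = 10, seed = 3)
  expect_equal(sort(unique(plan$fold)), 1:10)
  expect_equal(nrow(plan), 100)
  expect_true(all(table(plan$fold) == 10))
  # each stratum of 25 spreads over 10 folds within +-1 of 2.5
  tab <- table(plan$stratum, plan$fold)
  expect_true(all(tab >= 2 & tab <= 3))
  # determinism
  plan2 <- make_folds(records, k = 10, seed = 3)
  expect_identical(plan$fold, plan2$fold)
  plan3 <- make_folds(records, k = 10, seed = 4)
  expect_false(identical(plan$fold, plan3$fold))
})

test_that("strata smaller than k are merged with a warning", {
  records <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:30),
    sex = c(rep("female", 27), rep("male", 3)),
    diagnosis = "negative")
  expect_warning(plan <- make_folds(records, k = 5, seed = 1), "merged")
  expect_equal(sort(unique(plan$fold)), 1:5)
  expect_equal(nrow(plan), 30)
})

test_that("network specs expose both scales with the printed defaults", {
  s <- network_spec(10, "regression")
  expect_equal(s$dropout, 0.25)
  layers <- tissuewise:::build_layers(s)
  expect_equal(layers[[1]]$cin, 10)
  p <- network_spec(10, "binary_classification", scale = "full")
  lp <- tissuewise:::build_layers(p)
  blocks <- Filter(function(l) l$type == "block", lp)
  expect_equal(vapply(blocks, function(b) length(b$convs), integer(1)),
               c(6L, 12L, 24L, 16L))
  expect_equal(blocks[[1]]$growth, 32)
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$weight_decay, 1e-5)
  expect_equal(cfg$batch_size, 30)
})

test_that("the tiny network memorizes five subjects", {
  tk <- toy_task(5, seed = 2)
  spec <- network_spec(2, "regression")
  fit <- train_task(tk$x, tk$y, spec,
                    train_config(epochs = 250, learning_rate = 3e-3, seed = 1))
  p <- predict(fit, tk$x)
  expect_lt(mean(abs(p - tk$y)), 0.15 * sd(tk$y))
})

test_that("training is bitwise reproducible given the seed", {
  tk <- toy_task(8, seed = 3)
  spec <- network_spec(2, "regression")
  cfg <- train_config(epochs = 3, learning_rate = 1e-3, seed = 11)
  f1 <- train_task(tk$x, tk$y, spec, cfg)
  f2 <- train_task(tk$x, tk$y, spec, cfg)
  expect_identical(tissuewise:::flatten_params(f1$layers),
                   tissuewise:::flatten_params(f2$layers))
  expect_identical(predict(f1, tk$x), predict(f2, tk$x))
})

test_that("channel mismatches and empty training sets are rejected", {
  tk <- toy_task(4)
  spec10 <- network_spec(10, "regression")
  expect_error(train_task(tk$x, tk$y, spec10, train_config(epochs = 1)),
               "channels")
  spec2 <- network_spec(2, "regression")
  fit <- train_task(tk$x, tk$y, spec2, train_config(epochs = 1))
  bad <- array(0, c(16, 16, 5, 2))
  expect_error(predict(fit, bad), "C = 2")
  expect_error(train_task(tk$x, numeric(0), spec2, train_config(epochs = 1)))
})

test_that("a constant target is fit to within tolerance", {
  tk <- toy_task(6, seed = 5)
  y <- rep(42, 6)
  spec <- network_spec(2, "regression")
  fit <- train_task(tk$x, y, spec, train_config(epochs = 5, seed = 2))
  expect_true(all(abs(predict(fit, tk$x) - 42) < 1))
})

test_that("classification outputs are probabilities and permute with subjects", {
  tk <- toy_task(10, seed = 6, task = "binary_classification")
  spec <- network_spec(2, "binary_classification")
  fit <- train_task(tk$x, tk$y, spec,
                    train_config(epochs = 10, learning_rate = 1e-3, seed = 3))
  p <- predict(fit, tk$x)
  expect_true(all(p >= 0 & p <= 1))
  perm <- c(3, 1, 2, 10, 4:9)
  expect_equal(predict(fit, tk$x[, , , perm]), p[perm])
  expect_error(train_task(tk$x, tk$y + 0.5, spec, train_config(epochs = 1)),
               "0/1")
})

test_that("validation checkpointing records and restores the best epoch", {
  tk <- toy_task(12, seed = 7)
  spec <- network_spec(2, "regression")
  fit <- train_task(tk$x[, , , 1:8], tk$y[1:8], spec,
                    train_config(epochs = 6, learning_rate = 3e-3, seed = 4),
                    x_val = tk$x[, , , 9:12], y_val = tk$y[9:12])
  h <- tidy(fit)
  expect_equal(nrow(h), 6)
  expect_false(anyNA(h$val_loss))
  expect_equal(fit$best_epoch, which.min(h$val_loss))
  g <- glance(fit)
  expect_equal(g$task, "regression")
  expect_gt(g$n_parameters, 1000)
})
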