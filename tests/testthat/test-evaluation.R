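test_that("regression metrics match direct arithmetic", {
  y <- c(1, 2, 3, 4); yhat <- c(2, 2, 4, 4)
  m <- regression_metrics(y, yhat)
  expect_equal(m$mae, mean(abs(y - yhat)))               # 0.5
  expect_equal(m$r2, 1 - sum((y - yhat)^2) / sum((y - 2.5)^2))
  expect_equal(m$r, cor(y, yhat))

  perfect <- regression_metrics(y, y)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$r, 1)

  m0 <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(m0$r2, 0)
  expect_true(is.na(m0$r))  # constant predictions: r undefined

  expect_error(regression_metrics(y, yhat[1:3]), "length")
  expect_error(regression_metrics(rep(1, 4), rep(1, 4)), "variance")
})

test_that("AUC follows the Mann-Whitney tie convention and the pair-count oracle", {
  expect_equal(auc_mann_whitney(c(0, 0, 1, 1), c(0.1, 0.6, 0.4, 0.8)), 0.75)
  expect_equal(auc_mann_whitney(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  expect_equal(auc_mann_whitney(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)

  set.seed(31)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # many ties
    expect_equal(auc_mann_whitney(y, s), brute_auc(y, s))
  }
  expect_error(auc_mann_whitney(rep(1, 5), runif(5)), "classes")
})

test_that("thresholded classification metrics are exact on separated scores", {
  y <- c(0, 0, 0, 1, 1, 1)
  m <- classification_metrics(y, c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$precision, 1)

  m2 <- classification_metrics(y, c(0.6, 0.2, 0.3, 0.7, 0.8, 0.4))
  expect_equal(m2$sensitivity, 2 / 3)
  expect_equal(m2$specificity, 2 / 3)
  expect_equal(m2$precision, 2 / 3)
})

test_that("bootstrap CI is deterministic, collapses when exact, and narrows with n", {
  mae_fn <- function(a, b) mean(abs(a - b))
  y <- rnorm(50); ci1 <- bootstrap_ci(mae_fn, y, y + 1, 200, seed = 4)
  ci2 <- bootstrap_ci(mae_fn, y, y + 1, 200, seed = 4)
  expect_identical(ci1, ci2)
  expect_equal(unname(ci1["lo"]), 1)   # constant error: CI collapses
  expect_equal(unname(ci1["hi"]), 1)

  set.seed(5)
  widths <- sapply(c(30, 300), function(n) {
    w <- replicate(20, {
      yy <- rnorm(n); yh <- yy + rnorm(n)
      ci <- bootstrap_ci(mae_fn, yy, yh, 200, seed = sample.int(1e6, 1))
      ci["hi"] - ci["lo"]
    })
    mean(w)
  })
  expect_lt(widths[2], widths[1])
  expect_error(bootstrap_ci(mae_fn, y, y, n_boot = 10), "n_boot")
})

test_that("Steiger's Z is zero for equal correlations and sign-symmetric", {
  s <- steiger_z(0.8, 0.8, 0.5, 100)
  expect_equal(s$z, 0)
  expect_equal(s$p_value, 1)

  a <- steiger_z(0.92, 0.85, 0.8, 499)
  b <- steiger_z(0.85, 0.92, 0.8, 499)
  expect_equal(a$z, -b$z)
  expect_equal(a$p_value, b$p_value)
  expect_error(steiger_z(1, 0.5, 0.2, 50), "correlations")
  expect_error(steiger_z(0.5, 0.4, 0.3, 3), "at least 4")
})

test_that("Steiger's Z agrees with a Monte-Carlo null reference", {
  # the closed form should place ~5% of null statistics beyond +-1.96
  set.seed(17)
  n <- 60
  z <- replicate(400, {
    y <- rnorm(n); A <- 0.6 * y + rnorm(n); B <- 0.6 * y + rnorm(n)
    steiger_test(y, A, B)$z
  })
  expect_lt(abs(mean(abs(z) > 1.96) - 0.05), 0.035)
  expect_lt(abs(sd(z) - 1), 0.15)  # statistic is approximately standard normal
})

test_that("DeLong's test is degenerate on identical scores and matches its AUC", {
  y <- c(0, 1, 0, 1, 1, 0, 1, 0)
  s <- c(0.2, 0.7, 0.4, 0.9, 0.6, 0.1, 0.8, 0.3)
  d <- delong_test(y, s, s)
  expect_equal(d$auc_diff, 0)
  expect_equal(d$p_value, 1)
  expect_equal(d$auc_a, auc_mann_whitney(y, s))

  set.seed(23)
  y2 <- rbinom(60, 1, 0.5); y2[1:2] <- c(0, 1)
  a <- y2 + rnorm(60); b <- y2 + rnorm(60)
  d2 <- delong_test(y2, a, b)
  d2r <- delong_test(y2, b, a)
  expect_equal(d2$z, -d2r$z)
  expect_equal(d2$p_value, d2r$p_value)
  expect_error(delong_test(rep(1, 6), runif(6), runif(6)), "classes")
  expect_error(delong_test(y, s, s[1:4]), "paired")
})

test_that("DeLong's test agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (i in 1:5) {
    y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
    a <- y + rnorm(50); b <- y + rnorm(50)
    mine <- delong_test(y, a, b)
    ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                          pROC::roc(y, b, quiet = TRUE), method = "delong")
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("binned confusion matrices conserve counts and diagonalize exactness", {
  y <- c(1, 5, 9, 13, 2, 6)
  edges <- c(0, 4, 8, 16)
  m <- binned_confusion(y, y, edges)
  expect_true(all(m[row(m) != col(m)] == 0))
  expect_equal(sum(diag(m)), length(y))

  yhat <- c(5, 5, 9, 3, 2, 6)
  m2 <- binned_confusion(y, yhat, edges)
  expect_equal(unname(rowSums(m2)),
               unname(as.vector(table(cut(y, edges, include.lowest = TRUE)))))
  expect_error(binned_confusion(y, c(yhat[-6], 20), edges), "outside")
  expect_error(binned_confusion(y, yhat, c(0, 0, 8)), "increasing")

  # quantile default covers skewed TMTV-like values spanning 0.1 to 2481
  set.seed(3)
  tm <- exp(runif(200, log(0.1), log(2481)))
  m3 <- binned_confusion(tm, tm * exp(rnorm(200, 0, 0.1)))
  expect_equal(sum(m3), 200)
})

test_that("metrics report carries bootstrap CIs containing the point estimate", {
  set.seed(9)
  y <- rnorm(60); yhat <- y + rnorm(60, 0, 0.5)
  rep <- metrics_report(y, yhat, "regression", n_boot = 200, seed = 2)
  expect_setequal(rep$metric, c("mae", "r2", "r"))
  expect_true(all(rep$ci_lo <= rep$estimate + 1e-12 &
                    rep$estimate <= rep$ci_hi + 1e-12))
  yb <- rbinom(60, 1, 0.5); yb[1:2] <- c(0, 1)
  repc <- metrics_report(yb, plogis(yb + rnorm(60)), "binary_classification",
                         n_boot = 200, seed = 2, fold = rep(1:3, 20))
  expect_true("auc" %in% repc$metric)
  expect_equal(nrow(attr(repc, "per_fold")), 3)
})
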