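#' Regression metrics: MAE, R-squared, Pearson's r
#'
#' `MAE = mean(|y - yhat|)`, `R2 = 1 - SSres/SStot`, and Pearson's
#' correlation coefficient.
#'
#' @param y ground-truth values.
#' @param yhat predicted values of the same length.
#' @return One-row tibble with `mae`, `r2`, `r`, `n`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0L)
    stop("y and yhat must have equal nonzero length")
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r <- if (ss_tot == 0 || sd(yhat) == 0) {
    if (ss_tot == 0) stop("zero variance in y: Pearson's r undefined")
    NA_real_
  } else cor(y, yhat)
  tibble::tibble(mae = mean(abs(y - yhat)),
                 r2 = 1 - ss_res / ss_tot,
                 r = r, n = length(y))
}

#' Mann-Whitney AUC
#'
#' Area under the ROC curve as the concordance probability: the fraction of
#' (positive, negative) pairs in which the positive scores higher, ties
#' counting one half.
#'
#' @param y 0/1 labels.
#' @param scores numeric scores.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(y, scores) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present for AUC")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Classification metrics: AUC, sensitivity, specificity, precision
#'
#' AUC by the Mann-Whitney formulation; the thresholded metrics at the given
#' score cutoff (predicted positive when `score >= threshold`).
#'
#' @param y 0/1 labels (both classes present).
#' @param scores scores or probabilities.
#' @param threshold decision cutoff, default 0.5.
#' @return One-row tibble with `auc`, `sensitivity`, `specificity`,
#'   `precision`, `n`.
#' @export
classification_metrics <- function(y, scores, threshold = 0.5) {
  if (length(y) != length(scores) || length(y) == 0L)
    stop("y and scores must have equal nonzero length")
  if (length(unique(y)) < 2L)
    stop("both classes must be present")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  tibble::tibble(
    auc = auc_mann_whitney(y, scores),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    n = length(y))
}

#' Percentile bootstrap confidence interval for a paired metric
#'
#' Resamples subjects with replacement and returns the 2.5/97.5 percentile
#' bounds of the metric over `n_boot` resamples.  Deterministic given `seed`.
#'
#' @param metric_fn function `(y, yhat) -> scalar`.
#' @param y,yhat paired vectors.
#' @param n_boot number of resamples (at least 100).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return Named numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(metric_fn, y, yhat, n_boot = 1000, seed = 1,
                         conf = 0.95) {
  n <- length(y)
  stopifnot(length(yhat) == n)
  if (n_boot < 100) stop("n_boot must be at least 100")
  if (n < 2) stop("too few subjects to resample")
  a <- (1 - conf) / 2
  with_seed(seed, {
    stat <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      metric_fn(y[idx], yhat[idx])
    }, numeric(1))
    ci <- unname(quantile(stat, c(a, 1 - a), type = 7))
  })
  c(lo = ci[1], hi = ci[2])
}

#' Steiger's Z-test for two dependent, overlapping correlations
#'
#' Compares `r1 = cor(y, yhat_A)` against `r2 = cor(y, yhat_B)` when both
#' models predict the same ground truth `y`; `r12 = cor(yhat_A, yhat_B)`
#' captures the predictions' dependence.  Uses Fisher z-transforms with the
#' Steiger (1980) mean-correlation simplification of the Dunn-Clark
#' covariance; two-sided normal p-value.
#'
#' @param r1,r2 correlations of each model's predictions with the shared
#'   ground truth, in (-1, 1).
#' @param r12 correlation between the two prediction vectors.
#' @param n number of paired observations (at least 4).
#' @return One-row tibble with `z`, `p_value`, `r1`, `r2`, `r12`, `n`.
#' @export
steiger_z <- function(r1, r2, r12, n) {
  if (n < 4) stop("n must be at least 4")
  if (any(abs(c(r1, r2)) >= 1)) stop("correlations must lie in (-1, 1)")
  if (abs(r12) > 1) stop("r12 must lie in [-1, 1]")
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  if (z1 == z2) {
    z <- 0
  } else if (r12 >= 1) {
    z <- sign(z1 - z2) * Inf   # perfectly dependent predictions, zero variance
  } else {
    rm2 <- (r1^2 + r2^2) / 2
    f <- min((1 - r12) / (2 * (1 - rm2)), 1)
    h <- (1 - f * rm2) / (1 - rm2)
    z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))
  }
  tibble::tibble(z = z, p_value = 2 * pnorm(-abs(z)),
                 r1 = r1, r2 = r2, r12 = r12, n = as.integer(n))
}

#' @rdname steiger_z
#' @param y shared ground truth.
#' @param yhat_a,yhat_b the two models' paired predictions.
#' @export
steiger_test <- function(y, yhat_a, yhat_b) {
  stopifnot(length(y) == length(yhat_a), length(y) == length(yhat_b))
  steiger_z(cor(y, yhat_a), cor(y, yhat_b), cor(yhat_a, yhat_b), length(y))
}

# DeLong structural components: for each positive, the mean of the
# Mann-Whitney kernel against all negatives (and vice versa).
delong_components <- function(y, scores) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi),
       auc = mean(psi))
}

#' DeLong's test for two correlated ROC curves
#'
#' Tests the difference between two AUCs computed from paired scores on the
#' same subjects, using the structural-components estimate of the variance
#' of the AUC difference; two-sided normal p-value.
#'
#' @param y 0/1 labels (both classes present).
#' @param scores_a,scores_b the two models' scores, paired with `y`.
#' @return One-row tibble with `auc_a`, `auc_b`, `auc_diff`, `z`, `p_value`,
#'   `n`.
#' @export
delong_test <- function(y, scores_a, scores_b) {
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    stop("scores must be paired with y")
  if (length(unique(y)) < 2L)
    stop("both classes must be present")
  ca <- delong_components(y, scores_a)
  cb <- delong_components(y, scores_b)
  m <- length(ca$v10); n0 <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- ca$auc - cb$auc
  if (var_diff <= 0) {
    z <- if (abs(d) < .Machine$double.eps^0.5) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, auc_diff = d,
                 z = z, p_value = 2 * pnorm(-abs(z)), n = length(y))
}

#' Confusion matrix for a binned continuous target
#'
#' Bins ground truth and predictions with shared strictly increasing edges
#' and cross-tabulates them (rows = ground-truth bin, columns = predicted
#' bin).  Default edges are ground-truth quantiles.
#'
#' @param y,yhat paired continuous values.
#' @param edges strictly increasing bin edges covering all observed values;
#'   `NULL` for quantile-based edges.
#' @param n_bins number of quantile bins when `edges` is `NULL`.
#' @return A `binned_confusion`: integer matrix with bin-interval dimnames.
#' @export
binned_confusion <- function(y, yhat, edges = NULL, n_bins = 6) {
  stopifnot(length(y) == length(yhat))
  if (is.null(edges)) {
    edges <- unique(quantile(y, probs = seq(0, 1, length.out = n_bins + 1)))
    rng <- range(c(y, yhat))
    edges[1] <- min(edges[1], rng[1])
    edges[length(edges)] <- max(edges[length(edges)], rng[2])
  }
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  if (any(y < edges[1] | y > edges[length(edges)]) ||
      any(yhat < edges[1] | yhat > edges[length(edges)]))
    stop("values outside the bin edges")
  by <- cut(y, edges, include.lowest = TRUE)
  bh <- cut(yhat, edges, include.lowest = TRUE)
  m <- table(truth = by, predicted = bh)
  structure(unclass(m), class = c("binned_confusion", "matrix"))
}

#' @rdname binned_confusion
#' @param object a `binned_confusion`.
#' @param ... ignored.
#' @method autoplot binned_confusion
#' @export
autoplot.binned_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_viridis_c(name = "count") +
    ggplot2::labs(x = "predicted bin", y = "ground-truth bin")
}

#' Full metrics report with bootstrap confidence intervals
#'
#' Computes the task metrics and a percentile-bootstrap 95% CI for each, in
#' long format.
#'
#' @param y ground truth (0/1 for classification).
#' @param yhat predictions (scores for classification).
#' @param task `"regression"` or `"binary_classification"`.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @param fold optional per-subject fold labels; adds a per-fold breakdown
#'   attribute.
#' @return A tibble `metric`, `estimate`, `ci_lo`, `ci_hi` (class
#'   `metrics_report`); per-fold summaries in `attr(, "per_fold")` when
#'   `fold` is given.
#' @export
metrics_report <- function(y, yhat, task = c("regression", "binary_classification"),
                           n_boot = 1000, seed = 1, fold = NULL) {
  task <- match.arg(task)
  if (task == "regression") {
    fns <- list(mae = function(a, b) mean(abs(a - b)),
                r2 = function(a, b) 1 - sum((a - b)^2) / sum((a - mean(a))^2),
                r = function(a, b) suppressWarnings(cor(a, b)))
    point <- regression_metrics(y, yhat)
  } else {
    fns <- list(auc = auc_mann_whitney,
                sensitivity = function(a, b) classification_metrics(a, b)$sensitivity,
                specificity = function(a, b) classification_metrics(a, b)$specificity,
                precision = function(a, b) classification_metrics(a, b)$precision)
    point <- classification_metrics(y, yhat)
  }
  rows <- purrr::imap(fns, function(f, nm) {
    ci <- tryCatch(bootstrap_ci(f, y, yhat, n_boot = n_boot, seed = seed),
                   error = function(e) c(lo = NA_real_, hi = NA_real_))
    tibble::tibble(metric = nm, estimate = point[[nm]],
                   ci_lo = ci[["lo"]], ci_hi = ci[["hi"]])
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(fold)) {
    per_fold <- dplyr::group_modify(
      dplyr::group_by(tibble::tibble(y = y, yhat = yhat, fold = fold), .data$fold),
      function(d, key) {
        if (task == "regression") regression_metrics(d$y, d$yhat)
        else tryCatch(classification_metrics(d$y, d$yhat),
                      error = function(e) tibble::tibble(auc = NA_real_))
      })
    attr(out, "per_fold") <- dplyr::ungroup(per_fold)
  }
  class(out) <- c("metrics_report", class(out))
  out
}
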