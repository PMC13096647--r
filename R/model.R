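#' Specify the densely-connected CNN
#'
#' Defines the network layout used for collage regression/classification: an
#' initial strided convolution, densely-connected convolution blocks (each
#' layer's output concatenated onto its input), average-pool transitions,
#' global average pooling, dropout, and a single linear output unit (raw
#' value for regression, logit for classification).
#'
#' Two scales are provided.  `"tiny"` (two blocks of two 3x3 layers, growth
#' 12) trains in minutes on one CPU and is the scale exercised throughout the
#' tests.  `"full"` follows the DenseNet-121 layout (four blocks of
#' 6/12/24/16 layers, growth 32, 1x1 bottlenecks, halving transitions); it is
#' instantiable but far too large for CPU training.  Composite layers are
#' Conv-ReLU; batch normalization is not used.
#'
#' @param input_channels number of collage channels the first convolution
#'   accepts (10 for the full tissue-wise input; 5, 2, 1 for ablations).
#' @param task `"regression"` or `"binary_classification"`.
#' @param scale `"tiny"` or `"full"`.
#' @param dropout dropout rate on the pooled feature vector (default 0.25).
#' @return A `network_spec`.
#' @export
network_spec <- function(input_channels, task = c("regression", "binary_classification"),
                         scale = c("tiny", "full"), dropout = 0.25) {
  task <- match.arg(task)
  scale <- match.arg(scale)
  stopifnot(input_channels >= 1, dropout >= 0, dropout < 1)
  structure(list(input_channels = as.integer(input_channels), task = task,
                 scale = scale, dropout = dropout),
            class = "network_spec")
}

#' Training configuration
#'
#' Hyperparameters default to the study protocol: smooth-L1 loss for
#' regression / binary cross-entropy for classification, Adam with learning
#' rate 1e-4 and weight decay 1e-5, batch size 30.  The epoch budget and
#' checkpointing rule are configurable (a fixed budget with a
#' best-validation-loss checkpoint by default).
#'
#' @param epochs fixed epoch budget.
#' @param learning_rate,weight_decay Adam hyperparameters.
#' @param batch_size minibatch size.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param checkpoint keep the weights of the best validation-loss epoch
#'   (when a validation set is supplied) rather than the last epoch.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 40, learning_rate = 1e-4,
                         weight_decay = 1e-5, batch_size = 30, seed = 1,
                         checkpoint = TRUE) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), checkpoint = isTRUE(checkpoint)),
            class = "train_config")
}

# ---- layer construction ----------------------------------------------------

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

new_conv <- function(k, stride, pad, cin, cout) {
  list(type = "conv", k = k, stride = stride, pad = pad, cin = cin, cout = cout,
       w = he_init(k, cin, cout), b = numeric(cout))
}

new_block <- function(nlayers, growth, cin, bottleneck = FALSE) {
  convs <- list()
  cur <- cin
  for (j in seq_len(nlayers)) {
    if (bottleneck) {
      convs[[j]] <- list(pre = new_conv(1, 1, 0, cur, 4 * growth),
                         main = new_conv(3, 1, 1, 4 * growth, growth))
    } else {
      convs[[j]] <- list(main = new_conv(3, 1, 1, cur, growth))
    }
    cur <- cur + growth
  }
  list(type = "block", convs = convs, cin = cin, cout = cur, growth = growth,
       bottleneck = bottleneck)
}

build_layers <- function(spec) {
  C <- spec$input_channels
  if (spec$scale == "tiny") {
    layers <- list(new_conv(3, 2, 1, C, 16))
    b1 <- new_block(2, 12, 16)
    layers <- c(layers, list(b1, list(type = "pool")))
    b2 <- new_block(2, 12, b1$cout)
    layers <- c(layers, list(b2))
    feat <- b2$cout
  } else {
    layers <- list(new_conv(7, 2, 3, C, 64), list(type = "pool"))
    cur <- 64
    sizes <- c(6, 12, 24, 16)
    for (s in seq_along(sizes)) {
      b <- new_block(sizes[s], 32, cur, bottleneck = TRUE)
      layers <- c(layers, list(b))
      cur <- b$cout
      if (s < length(sizes)) {
        half <- as.integer(cur / 2)
        layers <- c(layers, list(new_conv(1, 1, 0, cur, half), list(type = "pool")))
        cur <- half
      }
    }
    feat <- cur
  }
  layers <- c(layers, list(list(type = "gap"),
                           list(type = "dropout", rate = spec$dropout),
                           list(type = "linear", cin = feat,
                                w = rnorm(feat, sd = 0.01), b = 0)))
  layers
}

# ---- forward / backward ----------------------------------------------------

bind_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

fwd_conv_unit <- function(l, x) {
  y <- cpp_conv_fwd(x, l$w, l$b, l$stride, l$pad)
  mask <- y > 0
  list(out = y * mask, cache = list(x = x, mask = mask))
}

bwd_conv_unit <- function(l, cache, g) {
  gy <- g * cache$mask
  r <- cpp_conv_bwd(cache$x, l$w, gy, l$stride, l$pad)
  list(gx = r$gx, gw = r$gw, gb = r$gb)
}

fwd_layer <- function(l, h, train) {
  switch(l$type,
    conv = fwd_conv_unit(l, h),
    block = {
      caches <- vector("list", length(l$convs))
      cur <- h
      for (j in seq_along(l$convs)) {
        cj <- l$convs[[j]]
        if (!is.null(cj$pre)) {
          r0 <- fwd_conv_unit(cj$pre, cur)
          r1 <- fwd_conv_unit(cj$main, r0$out)
          caches[[j]] <- list(pre = r0$cache, main = r1$cache)
        } else {
          r1 <- fwd_conv_unit(cj$main, cur)
          caches[[j]] <- list(main = r1$cache)
        }
        cur <- bind_channels(cur, r1$out)
      }
      list(out = cur, cache = caches)
    },
    pool = {
      d <- dim(h)
      h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
      ia <- seq_len(h2) * 2L - 1L
      xh <- (h[ia, , , , drop = FALSE] + h[ia + 1L, , , , drop = FALSE]) / 2
      ja <- seq_len(w2) * 2L - 1L
      out <- (xh[, ja, , , drop = FALSE] + xh[, ja + 1L, , , drop = FALSE]) / 2
      list(out = out, cache = d)
    },
    gap = {
      d <- dim(h)
      m <- matrix(h, d[1] * d[2], d[3] * d[4])
      list(out = matrix(colMeans(m), d[3], d[4]), cache = d)
    },
    dropout = {
      if (train && l$rate > 0) {
        keep <- 1 - l$rate
        mask <- (matrix(runif(length(h)), nrow(h), ncol(h)) < keep) / keep
        list(out = h * mask, cache = mask)
      } else list(out = h, cache = NULL)
    },
    linear = list(out = colSums(h * l$w) + l$b, cache = h)
  )
}

bwd_layer <- function(l, cache, g) {
  switch(l$type,
    conv = bwd_conv_unit(l, cache, g),
    block = {
      # g covers the full concatenated output; peel layers in reverse,
      # accumulating gradients for earlier channels.
      gacc <- g
      gw <- vector("list", length(l$convs))
      for (j in rev(seq_along(l$convs))) {
        d <- dim(gacc)
        ncur <- d[3] - l$growth
        gj <- gacc[, , ncur + seq_len(l$growth), , drop = FALSE]
        gacc <- gacc[, , seq_len(ncur), , drop = FALSE]
        cj <- l$convs[[j]]
        if (!is.null(cj$pre)) {
          r1 <- bwd_conv_unit(cj$main, cache[[j]]$main, gj)
          r0 <- bwd_conv_unit(cj$pre, cache[[j]]$pre, r1$gx)
          gacc <- gacc + r0$gx
          gw[[j]] <- list(pre = list(gw = r0$gw, gb = r0$gb),
                          main = list(gw = r1$gw, gb = r1$gb))
        } else {
          r1 <- bwd_conv_unit(cj$main, cache[[j]]$main, gj)
          gacc <- gacc + r1$gx
          gw[[j]] <- list(main = list(gw = r1$gw, gb = r1$gb))
        }
      }
      list(gx = gacc, gconvs = gw)
    },
    pool = {
      d <- cache
      h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
      gx <- array(0, d)
      gi <- rep(seq_len(h2), each = 2L)
      gj <- rep(seq_len(w2), each = 2L)
      gx[seq_len(h2 * 2L), seq_len(w2 * 2L), , ] <-
        g[gi, gj, , , drop = FALSE] / 4
      list(gx = gx)
    },
    gap = {
      d <- cache
      gx <- array(rep(as.vector(g), each = d[1] * d[2]) / (d[1] * d[2]), d)
      list(gx = gx)
    },
    dropout = list(gx = if (is.null(cache)) g else g * cache),
    linear = list(gx = outer(l$w, g), gw = as.vector(cache %*% g),
                  gb = sum(g))
  )
}

cnn_forward <- function(layers, x, train = FALSE, keep_out = NULL) {
  caches <- vector("list", length(layers))
  h <- x
  kept <- NULL
  for (i in seq_along(layers)) {
    r <- fwd_layer(layers[[i]], h, train)
    h <- r$out
    caches[[i]] <- r$cache
    if (!is.null(keep_out) && i == keep_out)
      kept <- h
  }
  list(out = as.vector(h), caches = caches, kept = kept)
}

# Backprop dLoss/dout (vector over the batch) through the network; returns
# parameter gradients (parallel to the layer list) and, optionally, the
# gradient with respect to the output of layer `grad_at` (the feature-map
# gradient Grad-CAM needs).
cnn_backward <- function(layers, caches, gout, grad_at = NULL) {
  grads <- vector("list", length(layers))
  g <- gout
  layer_grad <- NULL
  for (i in rev(seq_along(layers))) {
    r <- bwd_layer(layers[[i]], caches[[i]], g)
    grads[[i]] <- r[setdiff(names(r), "gx")]
    g <- r$gx
    if (!is.null(grad_at) && i == grad_at + 1L)
      layer_grad <- g
  }
  list(grads = grads, input_grad = g, layer_grad = layer_grad)
}

# ---- flat parameter access for the optimizer -------------------------------

flatten_params <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type %in% c("conv", "linear")) {
      out[[sprintf("L%d.w", i)]] <- l$w
      out[[sprintf("L%d.b", i)]] <- l$b
    } else if (l$type == "block") {
      for (j in seq_along(l$convs)) for (p in names(l$convs[[j]])) {
        out[[sprintf("L%d.%d.%s.w", i, j, p)]] <- l$convs[[j]][[p]]$w
        out[[sprintf("L%d.%d.%s.b", i, j, p)]] <- l$convs[[j]][[p]]$b
      }
    }
  }
  out
}

unflatten_params <- function(layers, flat) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type %in% c("conv", "linear")) {
      layers[[i]]$w <- flat[[sprintf("L%d.w", i)]]
      layers[[i]]$b <- flat[[sprintf("L%d.b", i)]]
    } else if (l$type == "block") {
      for (j in seq_along(l$convs)) for (p in names(l$convs[[j]])) {
        layers[[i]]$convs[[j]][[p]]$w <- flat[[sprintf("L%d.%d.%s.w", i, j, p)]]
        layers[[i]]$convs[[j]][[p]]$b <- flat[[sprintf("L%d.%d.%s.b", i, j, p)]]
      }
    }
  }
  layers
}

flatten_grads <- function(layers, grads) {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type %in% c("conv", "linear")) {
      out[[sprintf("L%d.w", i)]] <- grads[[i]]$gw
      out[[sprintf("L%d.b", i)]] <- grads[[i]]$gb
    } else if (l$type == "block") {
      for (j in seq_along(l$convs)) for (p in names(grads[[i]]$gconvs[[j]])) {
        out[[sprintf("L%d.%d.%s.w", i, j, p)]] <- grads[[i]]$gconvs[[j]][[p]]$gw
        out[[sprintf("L%d.%d.%s.b", i, j, p)]] <- grads[[i]]$gconvs[[j]][[p]]$gb
      }
    }
  }
  out
}

adam_step <- function(params, grads, state, lr, wd, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(params)) {
    g <- grads[[nm]] + wd * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- losses ----------------------------------------------------------------

smooth_l1 <- function(pred, y) {
  e <- pred - y
  a <- abs(e)
  loss <- mean(ifelse(a < 1, 0.5 * e^2, a - 0.5))
  list(loss = loss, grad = pmin(pmax(e, -1), 1) / length(e))
}

bce_logits <- function(z, y) {
  loss <- mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
  list(loss = loss, grad = (stats::plogis(z) - y) / length(z))
}

# ---- cross-validation folds ------------------------------------------------

#' Stratified k-fold assignment
#'
#' Partitions subjects into `k` validation folds, stratified by sex and
#' cancer type (the `diagnosis` column), so every fold preserves the cohort's
#' strata proportions to within one subject.  Strata smaller than `k` are
#' merged into a single pooled stratum with a warning.
#'
#' @param records tibble with `subject_id`, `sex` and `diagnosis` columns
#'   (e.g. from [derive_targets()]).
#' @param k number of folds (default 10).
#' @param seed RNG seed; the plan is deterministic given the seed.
#' @return The records with `stratum` and `fold` columns added.
#' @export
make_folds <- function(records, k = 10, seed = 1) {
  stopifnot(k >= 2, nrow(records) >= k)
  records <- dplyr::mutate(records,
                           stratum = paste(.data$sex, .data$diagnosis, sep = "/"))
  sizes <- table(records$stratum)
  small <- names(sizes)[sizes < k]
  if (length(small)) {
    warning("strata smaller than k merged: ", paste(small, collapse = ", "))
    records$stratum[records$stratum %in% small] <- "(merged)"
  }
  with_seed(seed, {
    records$fold <- NA_integer_
    fold_sizes <- integer(k)
    for (s in unique(records$stratum)) {
      idx <- which(records$stratum == s)
      idx <- idx[sample.int(length(idx))]
      nb <- length(idx) %/% k
      rem <- length(idx) - nb * k
      # whole multiples of k spread evenly; remainders go to the currently
      # smallest folds so overall fold sizes stay within one subject
      extras <- order(fold_sizes + runif(k))[seq_len(rem)]
      f <- c(rep(seq_len(k), nb), extras)
      records$fold[idx] <- f
      fold_sizes <- fold_sizes + tabulate(f, k)
    }
  })
  records
}

# ---- training --------------------------------------------------------------

#' Train the CNN on collage inputs
#'
#' Minibatch training with Adam on smooth-L1 (regression) or binary
#' cross-entropy (classification) loss.  Regression targets are z-scored
#' internally (statistics from the training set; predictions are returned in
#' the original units).  Fully reproducible given `config$seed`.
#'
#' @param x array `(H, W, C, N)` of collage channels (see [collage_stack()]).
#' @param y numeric targets: raw values for regression, 0/1 for
#'   classification.
#' @param spec a [network_spec()]; `spec$input_channels` must equal `dim(x)[3]`.
#' @param config a [train_config()].
#' @param x_val,y_val optional validation set for loss tracking and
#'   best-epoch checkpointing.
#' @param verbose print one line per epoch.
#' @return A `tw_model` with elements `layers` (weights), `spec`, `config`,
#'   `history` (per-epoch losses, see [tidy.tw_model()]) and `best_epoch`.
#' @export
train_task <- function(x, y, spec, config = train_config(),
                       x_val = NULL, y_val = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "network_spec"), inherits(config, "train_config"))
  d <- dim(x)
  if (length(d) != 4L)
    stop("x must be a (H, W, C, N) array")
  if (d[3] != spec$input_channels)
    stop("collage has ", d[3], " channels but the network expects ",
         spec$input_channels)
  n <- d[4]
  if (n == 0L) stop("empty training set")
  if (length(y) != n) stop("length(y) must match dim(x)[4]")
  regression <- spec$task == "regression"
  if (regression) {
    y_center <- mean(y)
    y_scale <- sd(y)
    if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
    yt <- (y - y_center) / y_scale
  } else {
    if (!all(y %in% c(0, 1))) stop("classification targets must be 0/1")
    y_center <- 0; y_scale <- 1
    yt <- y
  }
  yv <- NULL
  if (!is.null(x_val)) {
    stopifnot(dim(x_val)[3] == spec$input_channels)
    yv <- if (regression) (y_val - y_center) / y_scale else y_val
  }

  with_seed(config$seed, {
    layers <- build_layers(spec)
    params <- flatten_params(layers)
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    history <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                              val_loss = numeric())
    best <- list(loss = Inf, params = params, epoch = 0L)
    t_step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        fw <- cnn_forward(layers, xb, train = TRUE)
        lg <- if (regression) smooth_l1(fw$out, yt[idx]) else bce_logits(fw$out, yt[idx])
        ep_loss <- ep_loss + lg$loss * length(idx)
        bw <- cnn_backward(layers, fw$caches, lg$grad)
        gflat <- flatten_grads(layers, bw$grads)
        t_step <- t_step + 1L
        upd <- adam_step(params, gflat, state, config$learning_rate,
                         config$weight_decay, t_step)
        params <- upd$params
        state <- upd$state
        layers <- unflatten_params(layers, params)
      }
      train_loss <- ep_loss / n
      val_loss <- NA_real_
      if (!is.null(x_val)) {
        pv <- predict_raw(layers, x_val)
        val_loss <- if (regression) smooth_l1(pv, yv)$loss else bce_logits(pv, yv)$loss
        if (config$checkpoint && val_loss < best$loss)
          best <- list(loss = val_loss, params = params, epoch = ep)
      }
      history <- dplyr::bind_rows(history,
        tibble::tibble(epoch = ep, train_loss = train_loss, val_loss = val_loss))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %s", ep, train_loss,
                        ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
    }
    best_epoch <- config$epochs
    if (!is.null(x_val) && config$checkpoint && best$epoch > 0L) {
      layers <- unflatten_params(layers, best$params)
      best_epoch <- best$epoch
    }
    structure(list(layers = layers, spec = spec, config = config,
                   y_center = y_center, y_scale = y_scale,
                   history = history, best_epoch = best_epoch),
              class = "tw_model")
  })
}

# Forward pass in evaluation mode, chunked to bound memory.
predict_raw <- function(layers, x, chunk = 64L) {
  n <- dim(x)[4]
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    out[idx] <- cnn_forward(layers, x[, , , idx, drop = FALSE], train = FALSE)$out
  }
  out
}

#' Predict from a trained model
#'
#' @param object a `tw_model`.
#' @param x collage array `(H, W, C, N)`.
#' @param type `"response"` (original units / probability) or `"link"`
#'   (standardized value / logit).
#' @param ... ignored.
#' @return Numeric vector, one value per subject; probabilities lie in
#'   \[0, 1\] for classification.
#' @export
predict.tw_model <- function(object, x, type = c("response", "link"), ...) {
  type <- match.arg(type)
  d <- dim(x)
  if (length(d) != 4L || d[3] != object$spec$input_channels)
    stop("input must be (H, W, C, N) with C = ", object$spec$input_channels)
  z <- predict_raw(object$layers, x)
  if (type == "link") return(z)
  if (object$spec$task == "regression")
    z * object$y_scale + object$y_center
  else
    stats::plogis(z)
}

#' @export
print.tw_model <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$layers), length, numeric(1)))
  cat(sprintf("<tw_model> %s / %s scale, %d input channels, %s parameters\n",
              x$spec$task, x$spec$scale, x$spec$input_channels,
              format(np, big.mark = ",")))
  invisible(x)
}

#' Tidy the training history of a fitted model
#'
#' @param x a `tw_model`.
#' @param ... ignored.
#' @return Tibble with `epoch`, `train_loss`, `val_loss`.
#' @method tidy tw_model
#' @export
tidy.tw_model <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x a `tw_model`.
#' @param ... ignored.
#' @return Tibble with task, scale, parameter count, epochs, final and best
#'   losses.
#' @method glance tw_model
#' @export
glance.tw_model <- function(x, ...) {
  tibble::tibble(
    task = x$spec$task,
    scale = x$spec$scale,
    input_channels = x$spec$input_channels,
    n_parameters = sum(vapply(flatten_params(x$layers), length, numeric(1))),
    epochs = x$config$epochs,
    best_epoch = x$best_epoch,
    final_train_loss = utils::tail(x$history$train_loss, 1),
    best_val_loss = suppressWarnings(min(x$history$val_loss, na.rm = TRUE))
  )
}

#' Stack collages into a network input array
#'
#' @param collages list of `collage` objects on identical canvases.
#' @return Array `(H, W, C, N)`.
#' @export
collage_stack <- function(collages) {
  d <- dim(collages[[1]]$channels)
  x <- array(0, c(d, length(collages)))
  for (i in seq_along(collages)) {
    if (!identical(dim(collages[[i]]$channels), d))
      stop("collage ", i, " has a different canvas")
    x[, , , i] <- collages[[i]]$channels
  }
  x
}
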