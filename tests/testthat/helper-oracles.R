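# Independent oracles and small fixture builders used across the suite.

# Triple-loop brute-force projector for theta in {0, 90}.
brute_project <- function(v, axis, reduction) {
  d <- dim(v)
  keep <- setdiff(1:3, axis)
  out <- matrix(0, d[keep[1]], d[3])
  for (a in seq_len(d[keep[1]])) {
    for (z in seq_len(d[3])) {
      ray <- numeric(d[axis])
      for (b in seq_len(d[axis])) {
        idx <- integer(3)
        idx[axis] <- b; idx[keep[1]] <- a; idx[3] <- z
        ray[b] <- v[idx[1], idx[2], idx[3]]
      }
      out[a, z] <- if (reduction == "max") max(ray) else mean(ray)
    }
  }
  t(out)  # rows = longitudinal
}

# Exhaustive pair-count AUC oracle.
brute_auc <- function(y, scores) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Connected components by repeated neighbourhood growth (tiny grids only).
brute_components <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask == 1)
  for (s in idx) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      z <- (v - 1) %/% (d[1] * d[2])
      r <- (v - 1) %% (d[1] * d[2])
      y <- r %/% d[1]; x <- r %% d[1]
      for (k in seq_len(nrow(offs))) {
        xx <- x + offs$dx[k]; yy <- y + offs$dy[k]; zz <- z + offs$dz[k]
        if (xx < 0 || xx >= d[1] || yy < 0 || yy >= d[2] ||
            zz < 0 || zz >= d[3]) next
        u <- 1 + xx + d[1] * (yy + d[2] * zz)
        if (mask[u] == 1 && lab[u] == 0L) {
          lab[u] <- nxt
          queue <- c(queue, u)
        }
      }
    }
  }
  nxt
}

random_volume <- function(d, kind = "suv", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  volume_grid(array(runif(prod(d), 0, 10), d), c(1, 1, 1), kind)
}

# Minimal complete channel set on a shared small grid.
toy_channel_set <- function(d = c(8, 8, 12), seed = 1) {
  set.seed(seed)
  hu <- array(rnorm(prod(d), 0, 400), d)
  ct <- volume_grid(hu, c(2.04, 2.04, 3), "hu")
  suv <- volume_grid(array(runif(prod(d), 0, 8), d), c(2.04, 2.04, 3), "suv")
  apply_masks(ct, suv, tissue_masks(ct))
}

# Small-grid phantom parameters for fast unit tests (not the study scale).
# The lesion-volume spec scales down with the torso so draws always fit.
tiny_phantom_params <- function(...) {
  phantom_params(shape = c(48L, 48L, 80L),
                 tmtv_meanlog = log(8), tmtv_sdlog = 0.8,
                 tmtv_range = c(1, 30), lesion_count_max = 5,
                 min_lesion_ml = 1, ...)
}
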