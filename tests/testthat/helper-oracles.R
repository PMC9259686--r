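# Independent brute-force oracles used across the suite. These deliberately
# use the dumbest correct formulation (pixel loops, BFS flood fill, explicit
# normal equations) so they share no code with the implementation.

oracle_pixel_counts <- function(pred, gt) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && gt[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# BFS flood-fill labeling, connectivity 4 or 8.
oracle_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nbrs <- if (connectivity == 4) {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, ]
  }
  cur <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c] == 1 && lab[r, c] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r, c))
      lab[r, c] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nbrs))) {
          rr <- p[1] + nbrs[k, 1]; cc <- p[2] + nbrs[k, 2]
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              mask[rr, cc] == 1 && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# Explicit normal-equations least squares for the 6-term quadratic surface.
oracle_poly_fit <- function(image, keep_mask) {
  h <- nrow(image); w <- ncol(image)
  rows <- c(); cols <- c(); z <- c()
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (keep_mask[r, c] == 1) {
      rows <- c(rows, r); cols <- c(cols, c); z <- c(z, image[r, c])
    }
  }
  x <- (cols - 1) / (w - 1) * 2 - 1
  y <- (rows - 1) / (h - 1) * 2 - 1
  X <- cbind(1, x, y, x^2, x * y, y^2)
  solve(t(X) %*% X, t(X) %*% z)[, 1]
}

# Exhaustive IoU sweep: mean per-image IoU at each threshold.
oracle_threshold_sweep <- function(maps, gts, grid) {
  sapply(grid, function(th) {
    ious <- c()
    for (i in seq_along(maps)) {
      pred <- maps[[i]] > th
      gt <- gts[[i]] > 0
      un <- sum(pred | gt)
      if (un > 0) ious <- c(ious, sum(pred & gt) / un)
    }
    if (length(ious) == 0) NA_real_ else mean(ious)
  })
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

random_mask <- function(h, w, p) matrix(rbinom(h * w, 1, p), h, w)

# Small toy separable dataset: bright speckled disk on a dark field vs
# blank noisy field (for fast classifier tests).
toy_classif_data <- function(n_per_class = 20, size = 32, seed = 1) {
  with_seed_local(seed, {
    imgs <- list(); labs <- character(0)
    for (i in seq_len(n_per_class * 2)) {
      img <- matrix(rnorm(size * size, 1000, 50), size, size)
      lab <- if (i <= n_per_class) "clean" else "artifact"
      if (lab == "artifact") {
        r0 <- runif(1, size * 0.3, size * 0.7)
        c0 <- runif(1, size * 0.3, size * 0.7)
        R <- matrix(seq_len(size), size, size)
        C <- matrix(seq_len(size), size, size, byrow = TRUE)
        disk <- (R - r0)^2 + (C - c0)^2 <= (size / 5)^2
        img[disk] <- img[disk] + 2000 + rnorm(sum(disk), 0, 400)
      }
      imgs[[i]] <- img
      labs <- c(labs, lab)
    }
    list(images = imgs, labels = labs)
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
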