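# Minimal batched CNN engine.
#
# Tensors are numeric arrays H x W x B x C (height, width, batch, channels;
# channels last so im2col reduces to contiguous column copies).
# Convolutions are 3x3, stride 1, zero-padded to "same" size, computed by
# im2col + one BLAS matrix multiply per layer so that mini-batches amortize
# interpreter overhead. Every forward primitive returns the output plus the
# cache its backward pass needs; backward passes return gradients w.r.t.
# inputs and parameters. Optimization is Adam. All randomness goes through
# the caller-provided RNG state (set.seed upstream).

# ---- im2col / col2im -------------------------------------------------------

# Patch matrix for a 3x3 "same" convolution.
# Rows run over (h fastest, then w, then batch); columns over
# (kernel offset major, input channel minor).

# ---- layer primitives ------------------------------------------------------

conv_init <- function(c_in, c_out, kernel = 3L) {
  fan_in <- kernel * kernel * c_in
  list(W = matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)),
                  fan_in, c_out),
       b = numeric(c_out))
}

conv3_fwd <- function(x, par) {
  d <- dim(x)
  y <- conv3_fwd_cpp(x, par$W, par$b, d[1], d[2], d[3], d[4])
  list(y = y, cache = list(x = x, d = d))
}

conv3_bwd <- function(dy, cache, par) {
  d <- cache$d
  out <- conv3_bwd_cpp(dy, cache$x, par$W, d[1], d[2], d[3], d[4])
  list(dx = out$dx, dW = out$dW, db = out$db)
}

conv1x1_init <- function(c_in, c_out) {
  list(W = matrix(stats::rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out),
       b = numeric(c_out))
}

conv1x1_fwd <- function(x, par) {
  d <- dim(x)
  Xm <- matrix(x, d[1] * d[2] * d[3], d[4])
  Y <- sweep(Xm %*% par$W, 2L, par$b, "+")
  y <- array(Y, c(d[1], d[2], d[3], ncol(par$W)))
  list(y = y, cache = list(Xm = Xm, d = d))
}

conv1x1_bwd <- function(dy, cache, par) {
  d <- cache$d
  dYm <- matrix(dy, d[1] * d[2] * d[3], dim(dy)[4])
  list(dx = array(dYm %*% t(par$W), d),
       dW = crossprod(cache$Xm, dYm),
       db = colSums(dYm))
}

relu_fwd <- function(x) {
  m <- x > 0
  list(y = x * m, cache = m)
}
relu_bwd <- function(dy, mask) dy * mask

# 2x2 max pooling, stride 2. Ties route the gradient to the first maximal
# position in (top-left, bottom-left, top-right, bottom-right) order.
maxpool2_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  s <- list(x[i1, j1, , , drop = FALSE], x[i2, j1, , , drop = FALSE],
            x[i1, j2, , , drop = FALSE], x[i2, j2, , , drop = FALSE])
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  taken <- array(FALSE, dim(y))
  masks <- vector("list", 4L)
  for (k in 1:4) {
    m <- (s[[k]] == y) & !taken
    taken <- taken | m
    masks[[k]] <- m
  }
  list(y = y, cache = list(masks = masks, d = d))
}

maxpool2_bwd <- function(dy, cache) {
  d <- cache$d
  dx <- array(0, d)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  dx[i1, j1, , ] <- dy * cache$masks[[1]]
  dx[i2, j1, , ] <- dx[i2, j1, , , drop = FALSE] + dy * cache$masks[[2]]
  dx[i1, j2, , ] <- dx[i1, j2, , , drop = FALSE] + dy * cache$masks[[3]]
  dx[i2, j2, , ] <- dx[i2, j2, , , drop = FALSE] + dy * cache$masks[[4]]
  dx
}

# Nearest-neighbour x2 upsampling.
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  dy[i1, j1, , , drop = FALSE] + dy[i2, j1, , , drop = FALSE] +
    dy[i1, j2, , , drop = FALSE] + dy[i2, j2, , , drop = FALSE]
}

concat_fwd <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- a
  y[, , , da[4] + seq_len(db[4])] <- b
  list(y = y, na = da[4])
}

concat_bwd <- function(dy, na) {
  list(da = dy[, , , seq_len(na), drop = FALSE],
       db = dy[, , , -seq_len(na), drop = FALSE])
}

# Global average pooling: H x W x B x C -> B x C.
gap_fwd <- function(x) {
  d <- dim(x)
  Xm <- matrix(x, d[1] * d[2], d[3] * d[4])
  y <- matrix(colMeans(Xm), d[3], d[4])
  list(y = y, d = d)
}

gap_bwd <- function(dy, d) {
  per_px <- dy / (d[1] * d[2])                       # B x C
  array(rep(per_px, each = d[1] * d[2]), d)
}

# Global max pooling: H x W x B x C -> B x C. The gradient routes to the
# first maximal pixel of each feature map.
gmp_fwd <- function(x) {
  d <- dim(x)
  Xm <- matrix(x, d[1] * d[2], d[3] * d[4])
  am <- max.col(t(Xm), ties.method = "first")
  y <- matrix(Xm[cbind(am, seq_len(ncol(Xm)))], d[3], d[4])
  list(y = y, am = am, d = d)
}

gmp_bwd <- function(dy, cache) {
  d <- cache$d
  g <- matrix(0, d[1] * d[2], d[3] * d[4])
  g[cbind(cache$am, seq_len(ncol(g)))] <- as.vector(dy)
  array(g, d)
}

dense_init <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

dense_fwd <- function(x, par) {
  list(y = sweep(x %*% par$W, 2L, par$b, "+"), cache = x)
}

dense_bwd <- function(dy, cache, par) {
  list(dx = dy %*% t(par$W), dW = crossprod(cache, dy), db = colSums(dy))
}

# ---- losses ----------------------------------------------------------------

# Softmax cross-entropy. logits: B x K; target: integer class index (1-based).
softmax_xent <- function(logits, target) {
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), target)], 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(n), target)] <- dlogits[cbind(seq_len(n), target)] - 1
  list(loss = loss, p = p, dlogits = dlogits / n)
}

# Numerically stable pixel-wise binary cross-entropy on logits.
sigmoid_bce <- function(z, t) {
  loss <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  dz <- (stats::plogis(z) - t) / length(z)
  list(loss = loss, dz = dz)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

# ---- learning-rate schedule ------------------------------------------------

#' Patience-based learning-rate schedule
#'
#' Reproduces the plateau rule used for both networks: the learning rate
#' starts at `initial_lr` and is divided by `factor` whenever the validation
#' loss has not improved for `patience` consecutive epochs; the stagnation
#' counter then restarts.
#'
#' @param val_losses numeric vector of per-epoch validation losses observed
#'   so far (in epoch order).
#' @param initial_lr starting learning rate (default 0.002).
#' @param factor reduction factor (default 10).
#' @param patience epochs without improvement that trigger a reduction
#'   (default 10).
#' @return numeric vector: the learning rate used at each epoch
#'   `1..length(val_losses) + 1` (the last element is the rate for the next
#'   epoch).
#' @export
lr_schedule <- function(val_losses, initial_lr = 0.002, factor = 10,
                        patience = 10) {
  lr <- initial_lr
  best <- Inf
  stale <- 0L
  out <- numeric(length(val_losses) + 1L)
  out[1L] <- lr
  for (i in seq_along(val_losses)) {
    if (val_losses[i] < best) {
      best <- val_losses[i]
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (stale >= patience) {
      lr <- lr / factor
      stale <- 0L
    }
    out[i + 1L] <- lr
  }
  out
}

# Stack a list of H x W matrices into an H x W x B x 1 tensor.
stack_images <- function(imgs) {
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  array(unlist(imgs, use.names = FALSE), c(H, W, length(imgs), 1L))
}
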