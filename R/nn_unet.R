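# U-Net encoder-decoder for per-pixel artifact probability.
#
# Full preset follows the published architecture: an encoder of 15
# convolutional 3x3/ReLU layers with 2x2 max pooling and a skip connection
# after every third layer, a 3-layer bottleneck, and a symmetric decoder of
# 15 convolutional layers with x2 nearest-neighbour upsampling after every
# third layer; 64 filters throughout; skips merge by channel concatenation;
# output head is a 1x1 convolution + sigmoid. The small preset keeps the
# every-3rd-layer motif at test scale: 6+6 encoder/decoder layers, 2
# bottleneck layers, 16 filters, 2 pooling stages.

unet_presets <- list(
  small = list(stages = 2L, convs_per_stage = 3L, bottleneck = 2L,
               filters = 16L),
  full  = list(stages = 5L, convs_per_stage = 3L, bottleneck = 3L,
               filters = 64L)
)

#' U-Net configuration
#'
#' @param preset `"full"` (published architecture: 15+15 encoder/decoder
#'   convolutions, 3 bottleneck convolutions, 64 filters, 5 pooling stages)
#'   or `"small"` (6+6+2 layers, 16 filters, 2 pooling stages).
#' @param seed integer seed for weight initialization.
#' @return a `unet_config` list; `size_multiple` gives the divisibility
#'   requirement on input sides (`2^stages`).
#' @export
unet_config <- function(preset = "small", seed = 1L) {
  preset <- match.arg(preset, names(unet_presets))
  p <- unet_presets[[preset]]
  structure(c(p, list(preset = preset, kernel = c(3L, 3L),
                      size_multiple = 2L^p$stages, seed = as.integer(seed))),
            class = "unet_config")
}

#' Build an untrained U-Net
#'
#' @param config a [unet_config()].
#' @return an `artseg_unet` model with randomly initialized weights (He
#'   initialization, deterministic given `config$seed`).
#' @export
build_unet <- function(config = unet_config()) {
  S <- config$stages; K <- config$convs_per_stage; f <- config$filters
  with_seed(config$seed, {
    enc <- vector("list", S)
    c_prev <- 1L
    for (s in seq_len(S)) {
      enc[[s]] <- lapply(seq_len(K), function(k) {
        conv_init(if (k == 1L) c_prev else f, f)
      })
      c_prev <- f
    }
    bot <- lapply(seq_len(config$bottleneck), function(k) conv_init(f, f))
    dec <- vector("list", S)
    for (s in seq_len(S)) {
      dec[[s]] <- lapply(seq_len(K), function(k) {
        conv_init(if (k == 1L) 2L * f else f, f)
      })
    }
    params <- list(enc = enc, bot = bot, dec = dec,
                   head = conv1x1_init(f, 1L))
    structure(list(params = params, config = config, history = NULL),
              class = "artseg_unet")
  })
}

# Forward pass to logits. x: H x W x 1 x B with H, W divisible by
# 2^stages. Returns logits and caches when train = TRUE.
unet_fwd <- function(params, x, train = FALSE) {
  S <- length(params$enc)
  skips <- vector("list", S)
  cache <- list(enc = vector("list", S), pool = vector("list", S),
                bot = vector("list", length(params$bot)),
                dec = vector("list", S), concat_n = integer(S))
  for (s in seq_len(S)) {
    cc <- vector("list", length(params$enc[[s]]))
    for (k in seq_along(params$enc[[s]])) {
      cv <- conv3_fwd(x, params$enc[[s]][[k]])
      rl <- relu_fwd(cv$y)
      x <- rl$y
      if (train) cc[[k]] <- list(conv = cv$cache, mask = rl$cache)
    }
    skips[[s]] <- x
    pl <- maxpool2_fwd(x)
    x <- pl$y
    if (train) { cache$enc[[s]] <- cc; cache$pool[[s]] <- pl$cache }
  }
  for (k in seq_along(params$bot)) {
    cv <- conv3_fwd(x, params$bot[[k]])
    rl <- relu_fwd(cv$y)
    x <- rl$y
    if (train) cache$bot[[k]] <- list(conv = cv$cache, mask = rl$cache)
  }
  for (s in rev(seq_len(S))) {
    x <- upsample2_fwd(x)
    cn <- concat_fwd(x, skips[[s]])
    x <- cn$y
    cache$concat_n[s] <- cn$na
    cc <- vector("list", length(params$dec[[s]]))
    for (k in seq_along(params$dec[[s]])) {
      cv <- conv3_fwd(x, params$dec[[s]][[k]])
      rl <- relu_fwd(cv$y)
      x <- rl$y
      if (train) cc[[k]] <- list(conv = cv$cache, mask = rl$cache)
    }
    if (train) cache$dec[[s]] <- cc
  }
  hd <- conv1x1_fwd(x, params$head)
  if (train) cache$head <- hd$cache
  list(logits = hd$y, cache = if (train) cache)
}

unet_bwd <- function(dlogits, fwd, params) {
  S <- length(params$enc)
  hb <- conv1x1_bwd(dlogits, fwd$cache$head, params$head)
  dx <- hb$dx
  grads <- list(enc = vector("list", S), bot = vector("list", length(params$bot)),
                dec = vector("list", S), head = list(W = hb$dW, b = hb$db))
  dskip <- vector("list", S)
  for (s in seq_len(S)) {                            # decoder, shallow->deep
    gc <- vector("list", length(params$dec[[s]]))
    for (k in rev(seq_along(params$dec[[s]]))) {
      cc <- fwd$cache$dec[[s]][[k]]
      bw <- conv3_bwd(relu_bwd(dx, cc$mask), cc$conv, params$dec[[s]][[k]])
      dx <- bw$dx
      gc[[k]] <- list(W = bw$dW, b = bw$db)
    }
    grads$dec[[s]] <- gc
    sp <- concat_bwd(dx, fwd$cache$concat_n[s])
    dskip[[s]] <- sp$db
    dx <- upsample2_bwd(sp$da)
  }
  for (k in rev(seq_along(params$bot))) {
    cc <- fwd$cache$bot[[k]]
    bw <- conv3_bwd(relu_bwd(dx, cc$mask), cc$conv, params$bot[[k]])
    dx <- bw$dx
    grads$bot[[k]] <- list(W = bw$dW, b = bw$db)
  }
  for (s in rev(seq_len(S))) {
    dx <- maxpool2_bwd(dx, fwd$cache$pool[[s]]) + dskip[[s]]
    gc <- vector("list", length(params$enc[[s]]))
    for (k in rev(seq_along(params$enc[[s]]))) {
      cc <- fwd$cache$enc[[s]][[k]]
      bw <- conv3_bwd(relu_bwd(dx, cc$mask), cc$conv, params$enc[[s]][[k]])
      dx <- bw$dx
      gc[[k]] <- list(W = bw$dW, b = bw$db)
    }
    grads$enc[[s]] <- gc
  }
  grads
}

# Count convolutional layers (excluding the 1x1 output head).
unet_conv_layer_count <- function(model) {
  cfg <- model$config
  cfg$stages * cfg$convs_per_stage * 2L + cfg$bottleneck
}

# Same normalization contract as the classifier: min-max to [0,1], then
# per-image standardization (keeps activations well scaled without batch
# normalization), then reflect-pad to the network's size multiple.
prep_unet_input <- function(img, multiple) {
  x <- minmax01(img)
  x <- (x - mean(x)) / (stats::sd(x) + 1e-8)
  pad_to_multiple(x, multiple)
}

#' Train the U-Net segmenter
#'
#' Optimizes pixel-wise binary cross-entropy with Adam under the same
#' plateau learning-rate schedule as the classifier; the weights of the
#' best-validation-loss epoch are returned. Works identically for
#' pseudo-label masks (ScoreCAM-U-Net mode) and ground-truth masks
#' (strongly supervised mode).
#'
#' @param model an `artseg_unet` from [build_unet()].
#' @param images,masks aligned lists of numeric matrices and binary masks
#'   (training split).
#' @param train a [train_config()].
#' @param val_images,val_masks validation split used for the schedule and
#'   model selection.
#' @return the model with trained `params` and a `history` data.frame.
#' @export
train_segmenter <- function(model, images, masks, train = train_config(),
                            val_images, val_masks) {
  stop_if_not(length(images) == length(masks), "images/masks must align")
  for (i in seq_along(images))
    check_same_shape(images[[i]], masks[[i]], "image and mask")
  mult <- model$config$size_multiple
  xs <- lapply(images, function(im) prep_unet_input(im, mult)$x)
  ms <- lapply(masks, function(m) pad_to_multiple(as_mask(m), mult)$x)
  vx <- lapply(val_images, function(im) prep_unet_input(im, mult)$x)
  vm <- lapply(val_masks, function(m) pad_to_multiple(as_mask(m), mult)$x)

  with_seed(derive_seed(model$config$seed, train$seed), {
    params <- model$params
    opt <- adam_init(params)
    n <- length(xs)
    bs <- train$batch_size
    val_losses <- numeric(0)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0), lr = numeric(0))
    best <- list(loss = Inf, params = params)
    lr <- train$initial_learning_rate
    for (epoch in seq_len(train$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        xb <- stack_images(xs[idx])
        tb <- stack_images(ms[idx])
        fwd <- unet_fwd(params, xb, train = TRUE)
        ls <- sigmoid_bce(fwd$logits, tb)
        grads <- unet_bwd(ls$dz, fwd, params)
        up <- adam_step(params, grads, opt, lr)
        params <- up$params; opt <- up$state
        ep_loss <- ep_loss + ls$loss * length(idx)
      }
      ep_loss <- ep_loss / n
      vl <- segmenter_loss(params, vx, vm, bs)
      val_losses <- c(val_losses, vl)
      history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                           val_loss = vl, lr = lr))
      if (vl < best$loss) best <- list(loss = vl, params = params)
      lr <- lr_schedule(val_losses, train$initial_learning_rate,
                        train$lr_reduction_factor,
                        train$lr_patience_epochs)[epoch + 1L]
    }
    model$params <- best$params
    model$history <- history
    model$best_val_loss <- best$loss
    model
  })
}

segmenter_loss <- function(params, xs, ms, bs) {
  n <- length(xs)
  total <- 0
  for (start in seq(1L, n, by = bs)) {
    sel <- start:min(start + bs - 1L, n)
    fwd <- unet_fwd(params, stack_images(xs[sel]))
    total <- total +
      sigmoid_bce(fwd$logits, stack_images(ms[sel]))$loss * length(sel)
  }
  total / n
}

#' Per-pixel artifact probability map
#'
#' Inputs whose sides are not divisible by the model's size multiple are
#' reflect-padded, and the prediction is cropped back to the original shape.
#'
#' @param model a (trained) `artseg_unet`.
#' @param image numeric matrix.
#' @return numeric matrix of the same shape as `image`, values in \[0, 1\].
#' @export
predict_proba <- function(model, image) {
  stop_if_not(is.matrix(image), "image must be a matrix")
  pp <- prep_unet_input(image, model$config$size_multiple)
  x <- stack_images(list(pp$x))
  logits <- unet_fwd(model$params, x)$logits[, , 1L, 1L]
  p <- stats::plogis(logits)
  p[seq_len(pp$orig[1]), seq_len(pp$orig[2]), drop = FALSE]
}

#' @export
print.artseg_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("artseg U-Net (%s preset): %d enc + %d dec + %d bottleneck convs, %d filters\n",
              cfg$preset, cfg$stages * cfg$convs_per_stage,
              cfg$stages * cfg$convs_per_stage, cfg$bottleneck, cfg$filters))
  cat(sprintf("  input sides must be divisible by %d\n", cfg$size_multiple))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, best validation loss %.4f\n",
                nrow(x$history), x$best_val_loss))
  invisible(x)
}
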