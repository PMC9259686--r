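# Clean-vs-artifact image classifier: a small residual CNN trained from
# image-level labels. Each stage is conv-relu followed by a two-convolution
# identity residual block; 2x2 max pooling separates stages. Class scores
# come from global max pooling and a dense softmax head: artifacts are
# spatially sparse, so the strongest local texture response, not the field
# average, is the discriminative statistic. The "small" preset is sized for
# desk-scale images (96-128 px); "full" is the same design scaled up for
# full-resolution fields.

# pool_after: which residual stages are followed by 2x2 max pooling. The
# last stage stays at a higher resolution so its activation maps (the
# Score-CAM stack) outline small artifacts less coarsely.
classifier_presets <- list(
  small = list(filters = c(8L, 16L, 16L), pool_after = c(TRUE, FALSE, TRUE),
               input_size = 96L),
  full  = list(filters = c(32L, 64L, 128L, 128L),
               pool_after = c(TRUE, TRUE, FALSE, TRUE), input_size = 224L)
)

#' Classifier configuration
#'
#' @param backbone_preset `"small"` (three residual stages, for test-scale
#'   images) or `"full"` (four wider stages for full-resolution fields).
#' @param input_size square input side in pixels; must be divisible by
#'   `2^n_stages` of the chosen preset.
#' @param seed integer seed controlling weight initialization and data order.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(backbone_preset = "small", input_size = NULL,
                              seed = 1L) {
  preset <- match.arg(backbone_preset, names(classifier_presets))
  p <- classifier_presets[[preset]]
  if (is.null(input_size)) input_size <- p$input_size
  n_pools <- sum(p$pool_after)
  stop_if_not(input_size %% (2^n_pools) == 0,
              sprintf("input_size must be divisible by %d", 2^n_pools))
  structure(list(backbone_preset = preset, filters = p$filters,
                 pool_after = p$pool_after,
                 input_size = as.integer(input_size), num_classes = 2L,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

classifier_init <- function(config) {
  f <- config$filters
  stages <- vector("list", length(f))
  c_prev <- 1L
  for (s in seq_along(f)) {
    stages[[s]] <- list(conv_in = conv_init(c_prev, f[s]),
                        conv_a = conv_init(f[s], f[s]),
                        conv_b = conv_init(f[s], f[s]))
    c_prev <- f[s]
  }
  list(stages = stages, head = dense_init(f[length(f)], config$num_classes))
}

res_stage_fwd <- function(x, par) {
  c1 <- conv3_fwd(x, par$conv_in); r1 <- relu_fwd(c1$y)
  c2 <- conv3_fwd(r1$y, par$conv_a); r2 <- relu_fwd(c2$y)
  c3 <- conv3_fwd(r2$y, par$conv_b)
  r3 <- relu_fwd(c3$y + r1$y)
  list(y = r3$y,
       cache = list(c1 = c1$cache, m1 = r1$cache, c2 = c2$cache,
                    m2 = r2$cache, c3 = c3$cache, m3 = r3$cache))
}

res_stage_bwd <- function(dy, cache, par) {
  dz <- relu_bwd(dy, cache$m3)
  b3 <- conv3_bwd(dz, cache$c3, par$conv_b)
  b2 <- conv3_bwd(relu_bwd(b3$dx, cache$m2), cache$c2, par$conv_a)
  dr1 <- b2$dx + dz                                  # identity skip
  b1 <- conv3_bwd(relu_bwd(dr1, cache$m1), cache$c1, par$conv_in)
  list(dx = b1$dx,
       grads = list(conv_in = list(W = b1$dW, b = b1$db),
                    conv_a = list(W = b2$dW, b = b2$db),
                    conv_b = list(W = b3$dW, b = b3$db)))
}

# Forward pass over a batch tensor. Returns logits, the activation stack of
# the last convolutional layer (pre-pooling), and caches when train = TRUE.
classifier_fwd <- function(params, x, train = FALSE, pool_after = NULL) {
  S <- length(params$stages)
  if (is.null(pool_after)) pool_after <- rep(TRUE, S)
  caches <- vector("list", S)
  pools <- vector("list", S)
  acts <- NULL
  for (s in seq_len(S)) {
    st <- res_stage_fwd(x, params$stages[[s]])
    if (s == S) acts <- st$y
    if (pool_after[s]) {
      pl <- maxpool2_fwd(st$y)
      x <- pl$y
      if (train) pools[[s]] <- pl$cache
    } else {
      x <- st$y
    }
    if (train) caches[[s]] <- st$cache
  }
  g <- gmp_fwd(x)
  hd <- dense_fwd(g$y, params$head)
  list(logits = hd$y, acts = acts,
       cache = if (train) list(stages = caches, pools = pools, gmp = g,
                               head = g$y))
}

classifier_bwd <- function(dlogits, fwd, params, pool_after = NULL) {
  hb <- dense_bwd(dlogits, fwd$cache$head, params$head)
  dx <- gmp_bwd(hb$dx, fwd$cache$gmp)
  S <- length(params$stages)
  if (is.null(pool_after)) pool_after <- rep(TRUE, S)
  gstages <- vector("list", S)
  for (s in rev(seq_len(S))) {
    if (pool_after[s]) dx <- maxpool2_bwd(dx, fwd$cache$pools[[s]])
    sb <- res_stage_bwd(dx, fwd$cache$stages[[s]], params$stages[[s]])
    dx <- sb$dx
    gstages[[s]] <- sb$grads
  }
  list(stages = gstages, head = list(W = hb$dW, b = hb$db))
}

# Per-image preprocessing: min-max normalize to [0,1], resize to the
# model's square input size when needed, then standardize to zero mean and
# unit variance (8- and 16-bit inputs coexist, and standardization keeps
# early-layer activations well scaled without batch normalization).
prep_classifier_input <- function(img, input_size) {
  x <- minmax01(img)
  if (nrow(x) != input_size || ncol(x) != input_size)
    x <- resize_bilinear(x, input_size, input_size)
  (x - mean(x)) / (stats::sd(x) + 1e-8)
}

label_to_index <- function(labels) {
  stop_if_not(all(labels %in% c("clean", "artifact")),
              "labels must be 'clean' or 'artifact'")
  ifelse(labels == "artifact", 2L, 1L)
}

#' Train the clean-vs-artifact classifier
#'
#' Optimizes binary cross-entropy with Adam. The learning rate starts at
#' `train$initial_learning_rate` and drops by `train$lr_reduction_factor`
#' whenever the validation loss stagnates for `train$lr_patience_epochs`
#' consecutive epochs. The returned model carries the weights of the epoch
#' with the best validation loss.
#'
#' @param data list with elements `train` and `val`, each a list holding
#'   `images` (list of numeric matrices) and `labels` (character vector of
#'   `"clean"`/`"artifact"`).
#' @param config a [classifier_config()].
#' @param train a [train_config()].
#' @return an `artseg_classifier` with elements `params`, `config`, and
#'   `history` (per-epoch train/val loss and learning rate).
#' @export
train_classifier <- function(data, config = classifier_config(),
                             train = train_config()) {
  stop_if_not(length(data$train$images) > 0 && length(data$val$images) > 0,
              "train and validation splits must be nonempty")
  tr_idx <- label_to_index(data$train$labels)
  va_idx <- label_to_index(data$val$labels)
  stop_if_not(length(unique(tr_idx)) == 2L,
              "training split must contain both classes")
  xs <- lapply(data$train$images, prep_classifier_input, config$input_size)
  vs <- lapply(data$val$images, prep_classifier_input, config$input_size)

  with_seed(config$seed, {
    params <- classifier_init(config)
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
        fwd <- classifier_fwd(params, xb, train = TRUE, config$pool_after)
        ls <- softmax_xent(fwd$logits, tr_idx[idx])
        grads <- classifier_bwd(ls$dlogits, fwd, params, config$pool_after)
        up <- adam_step(params, grads, opt, lr)
        params <- up$params; opt <- up$state
        ep_loss <- ep_loss + ls$loss * length(idx)
      }
      ep_loss <- ep_loss / n
      vl <- classifier_loss(params, vs, va_idx, bs, config$pool_after)
      val_losses <- c(val_losses, vl)
      history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                           val_loss = vl, lr = lr))
      if (vl < best$loss) best <- list(loss = vl, params = params)
      lr <- lr_schedule(val_losses, train$initial_learning_rate,
                        train$lr_reduction_factor,
                        train$lr_patience_epochs)[epoch + 1L]
    }
    structure(list(params = best$params, config = config, history = history,
                   best_val_loss = best$loss),
              class = "artseg_classifier")
  })
}

classifier_loss <- function(params, xs, idx, bs, pool_after = NULL) {
  n <- length(xs)
  total <- 0
  for (start in seq(1L, n, by = bs)) {
    sel <- start:min(start + bs - 1L, n)
    fwd <- classifier_fwd(params, stack_images(xs[sel]), FALSE, pool_after)
    total <- total + softmax_xent(fwd$logits, idx[sel])$loss * length(sel)
  }
  total / n
}

#' Classify images as clean or artifact-containing
#'
#' @param model an `artseg_classifier`.
#' @param images a single numeric matrix or a list of them.
#' @return matrix with one row per image and columns `clean`, `artifact`
#'   (softmax probabilities summing to 1).
#' @export
classify <- function(model, images) {
  if (is.matrix(images)) images <- list(images)
  xs <- lapply(images, prep_classifier_input, model$config$input_size)
  probs <- matrix(0, length(xs), 2L, dimnames = list(NULL, c("clean", "artifact")))
  bs <- 32L
  for (start in seq(1L, length(xs), by = bs)) {
    sel <- start:min(start + bs - 1L, length(xs))
    fwd <- classifier_fwd(model$params, stack_images(xs[sel]), FALSE,
                          model$config$pool_after)
    z <- fwd$logits - apply(fwd$logits, 1L, max)
    ez <- exp(z)
    probs[sel, ] <- ez / rowSums(ez)
  }
  probs
}

#' @export
print.artseg_classifier <- function(x, ...) {
  cat(sprintf("artseg classifier (%s preset, input %dpx, %d stages)\n",
              x$config$backbone_preset, x$config$input_size,
              length(x$config$filters)))
  cat(sprintf("  trained %d epochs, best validation loss %.4f\n",
              nrow(x$history), x$best_val_loss))
  invisible(x)
}

#' Training hyper-parameters
#'
#' Defaults mirror the published training procedure: Adam, binary
#' cross-entropy, initial learning rate 0.002 reduced tenfold after 10
#' stagnant validation epochs, 150 epochs.
#'
#' @param initial_learning_rate starting Adam learning rate.
#' @param epochs number of training epochs.
#' @param lr_reduction_factor factor the learning rate is divided by.
#' @param lr_patience_epochs consecutive non-improving validation epochs
#'   that trigger a reduction.
#' @param batch_size mini-batch size.
#' @param seed integer seed (data order; weight init comes from the model
#'   config seed).
#' @return a `train_config` list.
#' @export
train_config <- function(initial_learning_rate = 0.002, epochs = 150L,
                         lr_reduction_factor = 10, lr_patience_epochs = 10L,
                         batch_size = 16L, seed = 1L) {
  stop_if_not(initial_learning_rate > 0 && epochs >= 1 &&
                lr_reduction_factor > 0 && lr_patience_epochs >= 1 &&
                batch_size >= 1, "train_config values must be positive")
  stop_if_not(lr_patience_epochs < epochs, "patience must be below epochs")
  structure(list(initial_learning_rate = initial_learning_rate,
                 epochs = as.integer(epochs),
                 lr_reduction_factor = lr_reduction_factor,
                 lr_patience_epochs = as.integer(lr_patience_epochs),
                 batch_size = as.integer(batch_size),
                 loss = "binary cross-entropy", seed = as.integer(seed)),
            class = "train_config")
}
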