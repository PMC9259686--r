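# Score-CAM saliency: localizes the image regions that drive the
# artifact-class prediction, using only forward passes.
#
# Four steps: (1) extract the activation maps of the classifier's last
# convolutional layer; (2) upscale each map to input size (bilinear) and
# min-max normalize it to [0,1]; (3) multiply each normalized map with a
# copy of the (normalized) input and score every projected image with the
# classifier for the target class, softmax-normalizing the scores across
# maps into weights; (4) ReLU the weighted sum of the normalized maps and
# min-max normalize the result to [0,1].

# Core combination, independent of any concrete model: takes an activation
# stack, the normalized input, and a scorer function over projected images.
scorecam_from_stack <- function(stack, input, scorer) {
  stop_if_not(length(dim(stack)) == 3L && dim(stack)[3] >= 1L,
              "activation stack must be h x w x K with K >= 1")
  K <- dim(stack)[3]
  H <- nrow(input); W <- ncol(input)
  norm_maps <- vector("list", K)
  projected <- vector("list", K)
  for (k in seq_len(K)) {
    up <- resize_bilinear(matrix(stack[, , k], dim(stack)[1], dim(stack)[2]),
                          H, W)
    nm <- minmax01(up)
    norm_maps[[k]] <- nm
    projected[[k]] <- nm * input
  }
  w <- scorer(projected)
  stop_if_not(length(w) == K, "scorer must return one weight per map")
  sal <- matrix(0, H, W)
  for (k in seq_len(K)) sal <- sal + w[k] * norm_maps[[k]]
  minmax01(pmax(sal, 0))
}

#' Score-CAM saliency map for the artifact class
#'
#' The per-map weights are the target-class scores of the projected
#' inputs, softmax-normalized across the activation maps (the weighting of
#' the Score-CAM framework; a constant baseline score cancels inside the
#' softmax). Normalizing across maps concentrates weight on the maps whose
#' projection is most artifact-evoking instead of diluting the saliency
#' over every map the classifier still recognizes.
#'
#' @param model a trained `artseg_classifier`.
#' @param image numeric matrix (grayscale intensities, any scale).
#' @param target_class class whose score weights the activation maps
#'   (default `"artifact"`).
#' @return numeric matrix with the same dimensions as `image`, values in
#'   \[0, 1\].
#' @export
scorecam_map <- function(model, image, target_class = "artifact") {
  stop_if_not(is.matrix(image), "image must be a matrix")
  cls <- match.arg(target_class, c("clean", "artifact"))
  col_idx <- if (cls == "artifact") 2L else 1L
  size <- model$config$input_size
  x <- prep_classifier_input(image, size)
  fwd <- classifier_fwd(model$params, stack_images(list(x)), FALSE,
                        model$config$pool_after)
  acts <- fwd$acts[, , 1L, , drop = TRUE]            # h x w x K
  if (length(dim(acts)) == 2L) acts <- array(acts, c(dim(acts), 1L))
  scorer <- function(projected) {
    xb <- stack_images(projected)
    logits <- classifier_fwd(model$params, xb, FALSE,
                             model$config$pool_after)$logits
    s <- logits[, col_idx] - logits[, -col_idx]      # target-class score
    w <- exp(s - max(s))
    w / sum(w)
  }
  sal <- scorecam_from_stack(acts, x, scorer)
  if (nrow(image) != size || ncol(image) != size)
    sal <- pmin(pmax(resize_bilinear(sal, nrow(image), ncol(image)), 0), 1)
  sal
}

#' Binarize a saliency or probability map
#'
#' Pixels strictly greater than the threshold become foreground. The default
#' pseudo-label threshold is 0.05.
#'
#' @param map numeric matrix in \[0, 1\].
#' @param threshold scalar in \[0, 1\].
#' @return integer 0/1 matrix.
#' @export
binarize_map <- function(map, threshold = 0.05) {
  stop_if_not(is.matrix(map), "map must be a matrix")
  stop_if_not(threshold >= 0 && threshold <= 1, "threshold must lie in [0,1]")
  matrix(as.integer(map > threshold), nrow(map), ncol(map))
}

# Default threshold sweep; includes the published pseudo-label operating
# point 0.05 and the evaluation cutoff 0.001.
default_threshold_grid <- function() {
  c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5)
}

#' Select a binarization threshold by validation IoU
#'
#' Sweeps a threshold grid, computing the mean per-image pixel IoU between
#' the binarized maps and ground-truth masks, and returns the grid value
#' maximizing it. Ties break toward the smallest threshold. Images where
#' IoU is undefined (empty prediction and empty ground truth) are skipped
#' in the mean.
#'
#' @param maps list of saliency/probability matrices in \[0, 1\].
#' @param gt_masks list of binary matrices, aligned with `maps`.
#' @param grid numeric vector of candidate thresholds.
#' @return list with `threshold` (best value) and `table` (data.frame of
#'   threshold and mean IoU).
#' @export
select_threshold <- function(maps, gt_masks, grid = default_threshold_grid()) {
  stop_if_not(length(maps) >= 1L, "validation set must be nonempty")
  stop_if_not(length(maps) == length(gt_masks),
              "maps and masks must be aligned")
  stop_if_not(length(grid) >= 1L, "threshold grid must be nonempty")
  grid <- sort(grid)
  mean_iou <- vapply(grid, function(th) {
    ious <- vapply(seq_along(maps), function(i) {
      pred <- maps[[i]] > th
      gt <- gt_masks[[i]] > 0
      tp <- sum(pred & gt)
      un <- sum(pred | gt)
      if (un == 0) NA_real_ else tp / un
    }, numeric(1))
    if (all(is.na(ious))) NA_real_ else mean(ious, na.rm = TRUE)
  }, numeric(1))
  best <- grid[which.max(mean_iou)]                  # first max = smallest tie
  list(threshold = best,
       table = data.frame(threshold = grid, mean_iou = mean_iou))
}

#' Generate pseudo-label masks for segmenter training
#'
#' Artifact-labeled images get their binarized Score-CAM map; clean-labeled
#' images get an all-zero mask, so the segmenter also sees negative
#' supervision.
#'
#' @param model a trained `artseg_classifier`.
#' @param images list of numeric matrices.
#' @param labels character vector `"clean"`/`"artifact"`, aligned with
#'   `images`.
#' @param threshold binarization threshold (default 0.05).
#' @return list of integer 0/1 matrices, one per image.
#' @export
make_pseudolabels <- function(model, images, labels, threshold = 0.05) {
  stop_if_not(length(images) == length(labels),
              "every image needs an image-level label")
  label_to_index(labels)                             # validates values
  lapply(seq_along(images), function(i) {
    if (labels[i] == "clean") {
      matrix(0L, nrow(images[[i]]), ncol(images[[i]]))
    } else {
      binarize_map(scorecam_map(model, images[[i]]), threshold)
    }
  })
}
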