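# Two-stage inference (classifier gate -> U-Net segmentation -> published
# post-processing) and the full train-from-image-labels orchestration.

#' Post-processing configuration
#'
#' Published operating points: probability cutoffs 0.001 (ScoreCAM), 0.001
#' (ScoreCAM-U-Net) and 0.45 (strongly supervised U-Net); minimum object
#' sizes 1000 px (seven-cell-lines preset) and 500 px (CHO-M4R and LNCaP
#' presets).
#'
#' @param model one of `"scorecam_unet"`, `"unet"`, `"scorecam"` (sets the
#'   default cutoff).
#' @param dataset_preset one of `"seven_cell_lines"`, `"cho_m4r"`,
#'   `"lncap"` (sets the default minimum object size), or `NULL` to give
#'   `min_object_size` directly.
#' @param binarization_cutoff probability cutoff in \[0, 1\].
#' @param min_object_size minimum connected-component size in pixels.
#' @param connectivity 4 or 8 (default 8).
#' @return a `postprocess_config` list.
#' @export
postprocess_config <- function(model = c("scorecam_unet", "unet", "scorecam"),
                               dataset_preset = NULL,
                               binarization_cutoff = NULL,
                               min_object_size = NULL,
                               connectivity = 8) {
  model <- match.arg(model)
  if (is.null(binarization_cutoff))
    binarization_cutoff <- switch(model, scorecam_unet = 0.001,
                                  unet = 0.45, scorecam = 0.001)
  if (is.null(min_object_size)) {
    min_object_size <- if (is.null(dataset_preset)) 0L else
      switch(match.arg(dataset_preset,
                       c("seven_cell_lines", "cho_m4r", "lncap")),
             seven_cell_lines = 1000L, cho_m4r = 500L, lncap = 500L)
  }
  stop_if_not(binarization_cutoff >= 0 && binarization_cutoff <= 1,
              "binarization_cutoff must lie in [0, 1]")
  stop_if_not(min_object_size >= 0, "min_object_size must be >= 0")
  structure(list(model = model, binarization_cutoff = binarization_cutoff,
                 min_object_size = as.integer(min_object_size),
                 connectivity = connectivity),
            class = "postprocess_config")
}

#' Classify-then-segment artifact prediction
#'
#' If the classifier's artifact probability does not exceed the gate
#' threshold the image is deemed clean and an all-zero mask is returned;
#' otherwise the segmenter's probability map is binarized at the cutoff
#' and small objects are removed.
#'
#' @param image numeric matrix.
#' @param classifier an `artseg_classifier`.
#' @param segmenter an `artseg_unet`.
#' @param post a [postprocess_config()].
#' @param gate_threshold artifact-probability gate (default 0.5).
#' @return an `artifact_mask`: integer 0/1 matrix with a `provenance`
#'   attribute recording cutoff, minimum size and gate decision.
#' @export
predict_artifacts <- function(image, classifier, segmenter,
                              post = postprocess_config(),
                              gate_threshold = 0.5) {
  p_art <- classify(classifier, image)[1, "artifact"]
  gated <- p_art <= gate_threshold
  mask <- if (gated) {
    matrix(0L, nrow(image), ncol(image))
  } else {
    pm <- predict_proba(segmenter, image)
    remove_small_objects(binarize_map(pm, post$binarization_cutoff),
                         post$min_object_size, post$connectivity)
  }
  structure(mask, provenance = list(model = post$model,
                                    cutoff = post$binarization_cutoff,
                                    min_object_size = post$min_object_size,
                                    gate_threshold = gate_threshold,
                                    p_artifact = unname(p_art),
                                    gated_clean = gated))
}

#' Full weakly supervised training workflow
#'
#' Runs the train-time pipeline end to end: (1) train the clean/artifact
#' classifier on image-level labels; (2) compute Score-CAM maps for
#' training images; (3) select the pseudo-label binarization threshold on
#' validation maps by IoU when validation pixel masks exist, else use the
#' default 0.05; (4) binarize into pseudo-masks; (5) train the U-Net on
#' the pseudo-masks. Returns all stage artifacts plus a JSON-serializable
#' run report.
#'
#' @param images list of numeric matrices.
#' @param labels character vector of image-level labels.
#' @param split factor/character of `"train"`/`"val"`/`"test"`.
#' @param gt_masks optional list of pixel ground-truth masks (only the
#'   validation entries are used, for threshold selection).
#' @param classifier_cfg,unet_cfg model configurations.
#' @param train_cfg a [train_config()] for the classifier.
#' @param segmenter_train_cfg a [train_config()] for the U-Net; defaults
#'   to `train_cfg`.
#' @param threshold `"auto"` (select on validation) or a fixed numeric.
#' @param seed master seed.
#' @return list with `classifier`, `threshold` (pseudo-label cutoff),
#'   `threshold_table`, `pseudo_masks`, `segmenter`, `eval_cutoff` (the
#'   evaluation-time binarization cutoff, selected on validation maps by
#'   IoU when ground-truth masks are given), `eval_cutoff_table`, and a
#'   JSON-serializable `report`.
#' @export
run_full_training <- function(images, labels, split, gt_masks = NULL,
                              classifier_cfg = classifier_config(),
                              unet_cfg = unet_config(),
                              train_cfg = train_config(),
                              segmenter_train_cfg = train_cfg,
                              threshold = "auto", seed = 1L) {
  split <- as.character(split)
  stop_if_not(all(split %in% c("train", "val", "test")),
              "split must be train/val/test")
  tr <- split == "train"; va <- split == "val"
  stop_if_not(any(tr) && any(va), "train and val splits must be nonempty")

  classifier_cfg$seed <- derive_seed(seed, 1L)
  unet_cfg$seed <- derive_seed(seed, 2L)

  clf <- train_classifier(
    list(train = list(images = images[tr], labels = labels[tr]),
         val = list(images = images[va], labels = labels[va])),
    classifier_cfg, train_cfg)

  # Score-CAM maps for validation threshold selection and for pseudo-labels
  threshold_table <- NULL
  if (identical(threshold, "auto")) {
    va_art <- which(va & labels == "artifact")
    if (!is.null(gt_masks) && length(va_art) > 0) {
      va_maps <- lapply(images[va_art], function(im) scorecam_map(clf, im))
      sel <- select_threshold(va_maps, gt_masks[va_art])
      threshold <- sel$threshold
      threshold_table <- sel$table
    } else {
      threshold <- 0.05
    }
  }
  stop_if_not(is.numeric(threshold) && threshold >= 0 && threshold <= 1,
              "threshold must be 'auto' or a numeric in [0, 1]")

  pseudo <- make_pseudolabels(clf, images[tr], labels[tr], threshold)

  seg <- build_unet(unet_cfg)
  # U-Net validation targets: ground-truth masks when available, else
  # pseudo-labels of the validation images.
  val_masks <- if (!is.null(gt_masks)) {
    gt_masks[va]
  } else {
    make_pseudolabels(clf, images[va], labels[va], threshold)
  }
  seg <- train_segmenter(seg, images[tr], pseudo, segmenter_train_cfg,
                         images[va], val_masks)

  # Evaluation-time binarization cutoff: selected on validation probability
  # maps by pixel IoU when ground-truth masks exist (the same criterion the
  # published cutoffs were selected with); otherwise the ScoreCAM-U-Net
  # preset default applies.
  eval_cutoff <- postprocess_config("scorecam_unet")$binarization_cutoff
  eval_cutoff_table <- NULL
  if (!is.null(gt_masks)) {
    va_maps <- lapply(images[va], function(im) predict_proba(seg, im))
    sel2 <- select_threshold(va_maps, gt_masks[va])
    eval_cutoff <- sel2$threshold
    eval_cutoff_table <- sel2$table
  }

  report <- list(
    seed = seed,
    stages = list(
      classifier = list(preset = classifier_cfg$backbone_preset,
                        seed = classifier_cfg$seed,
                        epochs = nrow(clf$history),
                        best_val_loss = clf$best_val_loss),
      scorecam = list(n_train_maps = sum(tr & labels == "artifact")),
      threshold = list(value = threshold,
                       selected = !is.null(threshold_table)),
      pseudolabels = list(n_masks = length(pseudo),
                          positive_fraction =
                            mean(vapply(pseudo, mean, numeric(1)))),
      segmenter = list(preset = unet_cfg$preset, seed = unet_cfg$seed,
                       epochs = nrow(seg$history),
                       best_val_loss = seg$best_val_loss,
                       eval_cutoff = eval_cutoff)))
  list(classifier = clf, threshold = threshold,
       threshold_table = threshold_table, pseudo_masks = pseudo,
       segmenter = seg, eval_cutoff = eval_cutoff,
       eval_cutoff_table = eval_cutoff_table, report = report)
}
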