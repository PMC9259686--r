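# Evaluation suite: pixel-wise precision / recall / F1 / IoU, image-level
# classification F1, object-wise F1 over matched connected components, and
# pooled precision-recall curves. Metrics with an empty denominator are
# reported as NA (an explicit "undefined" flag), never silently as zero;
# aggregation skips undefined entries.

metrics_from_counts <- function(tp, fp, fn, tn = NA_integer_,
                                granularity = "pixel", n_units = NA_integer_) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else if (tp + fp + fn == 0) NA_real_ else 0
  iou <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_
  structure(list(precision = precision, recall = recall, f1 = f1, iou = iou,
                 counts = list(tp = tp, fp = fp, fn = fn, tn = tn),
                 granularity = granularity, n_units = n_units),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf("%s-level metrics (tp=%d fp=%d fn=%d): precision=%s recall=%s f1=%s iou=%s\n",
              x$granularity, x$counts$tp, x$counts$fp, x$counts$fn,
              fmt(x$precision), fmt(x$recall), fmt(x$f1), fmt(x$iou)))
  invisible(x)
}

#' Pixel-wise segmentation metrics
#'
#' @param pred_mask,gt_mask aligned binary matrices.
#' @return a `metrics_report` with precision, recall, F1 (harmonic mean)
#'   and IoU (`tp / (tp + fp + fn)`); undefined values are `NA`.
#' @export
pixel_metrics <- function(pred_mask, gt_mask) {
  p <- as_mask(pred_mask, "pred_mask"); g <- as_mask(gt_mask, "gt_mask")
  check_same_shape(p, g, "masks")
  tp <- sum(p == 1L & g == 1L)
  fp <- sum(p == 1L & g == 0L)
  fn <- sum(p == 0L & g == 1L)
  tn <- sum(p == 0L & g == 0L)
  metrics_from_counts(tp, fp, fn, tn, "pixel", length(p))
}

#' Image-level classification F1
#'
#' @param pred_labels,true_labels equal-length character vectors with
#'   values `"clean"`/`"artifact"`.
#' @param positive the positive class (default `"artifact"`).
#' @return a `metrics_report` at image granularity.
#' @export
image_level_f1 <- function(pred_labels, true_labels, positive = "artifact") {
  stop_if_not(length(pred_labels) == length(true_labels),
              "label vectors must have equal length")
  ok <- c("clean", "artifact")
  stop_if_not(all(pred_labels %in% ok) && all(true_labels %in% ok),
              "labels must be 'clean' or 'artifact'")
  p <- pred_labels == positive
  t <- true_labels == positive
  metrics_from_counts(sum(p & t), sum(p & !t), sum(!p & t), sum(!p & !t),
                      "image", length(p))
}

# IoU between one predicted and one ground-truth component (pixel index sets).
pair_iou <- function(a_idx, b_idx) {
  i <- length(intersect(a_idx, b_idx))
  u <- length(a_idx) + length(b_idx) - i
  if (u == 0) 0 else i / u
}

#' Object-wise F1 over matched connected components
#'
#' Components are extracted from both masks; candidate pairs are matched
#' one-to-one greedily by descending pairwise IoU; a pair counts as a true
#' positive iff its IoU reaches `iou_threshold`. Unmatched predictions are
#' false positives; unmatched ground-truth objects are false negatives.
#'
#' @param pred_mask,gt_mask aligned binary matrices.
#' @param iou_threshold minimum IoU for a valid match (default 0.5).
#' @param connectivity component connectivity (default 8).
#' @return a `metrics_report` at object granularity.
#' @export
object_f1 <- function(pred_mask, gt_mask, iou_threshold = 0.5,
                      connectivity = 8) {
  p_lab <- label_components(pred_mask, connectivity)
  g_lab <- label_components(gt_mask, connectivity)
  object_f1_from_labels(p_lab, g_lab, iou_threshold)
}

object_f1_from_labels <- function(p_lab, g_lab, iou_threshold = 0.5) {
  check_same_shape(p_lab, g_lab, "masks")
  np <- max(p_lab); ng <- max(g_lab)
  if (np == 0 && ng == 0)
    return(metrics_from_counts(0L, 0L, 0L, granularity = "object", n_units = 0L))
  pairs <- NULL
  if (np > 0 && ng > 0) {
    overlap <- table(factor(p_lab[p_lab > 0 & g_lab > 0],
                            levels = seq_len(np)),
                     factor(g_lab[p_lab > 0 & g_lab > 0],
                            levels = seq_len(ng)))
    p_size <- tabulate(p_lab[p_lab > 0], np)
    g_size <- tabulate(g_lab[g_lab > 0], ng)
    idx <- which(overlap > 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      inter <- overlap[idx]
      iou <- inter / (p_size[idx[, 1]] + g_size[idx[, 2]] - inter)
      ord <- order(-iou, idx[, 1], idx[, 2])
      used_p <- logical(np); used_g <- logical(ng)
      tp <- 0L
      for (k in ord) {
        i <- idx[k, 1]; j <- idx[k, 2]
        if (used_p[i] || used_g[j]) next
        used_p[i] <- TRUE; used_g[j] <- TRUE
        if (iou[k] >= iou_threshold) tp <- tp + 1L
      }
      pairs <- tp
    }
  }
  tp <- if (is.null(pairs)) 0L else pairs
  metrics_from_counts(tp, np - tp, ng - tp, granularity = "object",
                      n_units = np + ng)
}

#' Pooled precision-recall curve over score maps
#'
#' Pixel counts are pooled across all images at each threshold; the area
#' is the trapezoidal integral of precision over recall.
#'
#' @param score_maps list of numeric matrices in \[0, 1\].
#' @param gt_masks aligned list of binary matrices.
#' @param thresholds sorted numeric vector of cutoffs.
#' @return list with `curve` (data.frame threshold/precision/recall) and
#'   `auc`.
#' @export
pr_curve <- function(score_maps, gt_masks,
                     thresholds = seq(0.025, 0.975, by = 0.025)) {
  stop_if_not(length(score_maps) >= 1, "need at least one score map")
  stop_if_not(length(score_maps) == length(gt_masks),
              "maps and masks must be aligned")
  stop_if_not(!is.unsorted(thresholds), "thresholds must be sorted")
  scores <- unlist(lapply(score_maps, as.vector))
  gts <- unlist(lapply(gt_masks, function(m) as.vector(as_mask(m) == 1L)))
  n_pos <- sum(gts)
  rows <- lapply(thresholds, function(th) {
    pred <- scores > th
    tp <- sum(pred & gts)
    fp <- sum(pred & !gts)
    data.frame(threshold = th,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (n_pos > 0) tp / n_pos else NA_real_)
  })
  curve <- do.call(rbind, rows)
  ok <- stats::complete.cases(curve)
  cc <- curve[ok, , drop = FALSE]
  # integrate precision over recall (recall decreases with threshold)
  auc <- if (nrow(cc) >= 2) {
    o <- order(cc$recall)
    sum(diff(cc$recall[o]) *
          (utils::head(cc$precision[o], -1) + utils::tail(cc$precision[o], -1)) / 2)
  } else NA_real_
  list(curve = curve, auc = auc)
}

#' Aggregate per-image metric reports
#'
#' Per-image averaging (the default dataset aggregation); undefined
#' (`NA`) entries are skipped per metric. Pooled aggregation over summed
#' counts is also returned.
#'
#' @param reports list of `metrics_report` objects.
#' @return list with `per_image_mean` (named numeric) and `pooled` (a
#'   `metrics_report` over summed counts).
#' @export
aggregate_metrics <- function(reports) {
  stop_if_not(length(reports) >= 1, "need at least one report")
  take <- function(field) {
    v <- vapply(reports, `[[`, numeric(1), field)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  per_image <- c(precision = take("precision"), recall = take("recall"),
                 f1 = take("f1"), iou = take("iou"))
  csum <- function(field) sum(vapply(reports, function(r) r$counts[[field]],
                                     numeric(1)), na.rm = TRUE)
  pooled <- metrics_from_counts(csum("tp"), csum("fp"), csum("fn"),
                                csum("tn"),
                                granularity = reports[[1]]$granularity,
                                n_units = length(reports))
  list(per_image_mean = per_image, pooled = pooled)
}
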