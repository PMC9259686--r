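# Downstream impact analyses: how artifacts (and their removal) change
# nuclei segmentation scores, nucleus morphometry, fluorescence
# quantification and ligand-affinity (IC50) estimates.

#' Artifact-stratified nuclei segmentation evaluation
#'
#' Pixel metrics are computed after restricting both the prediction and
#' the ground truth to each region (inside artifacts, outside artifacts,
#' all). Object metrics assign each connected component to a region by
#' majority pixel overlap (ties to inside).
#'
#' @param nuclei_pred_mask,nuclei_gt_mask aligned binary matrices.
#' @param artifact_mask aligned binary matrix defining the inside region.
#' @param connectivity component connectivity for object metrics.
#' @return named list of per-region reports (`inside_artifacts`,
#'   `outside_artifacts`, `all`), each holding `pixel_report`,
#'   `object_report`, and `empty_region` flag.
#' @export
stratified_nuclei_eval <- function(nuclei_pred_mask, nuclei_gt_mask,
                                   artifact_mask, connectivity = 8) {
  p <- as_mask(nuclei_pred_mask, "nuclei_pred_mask")
  g <- as_mask(nuclei_gt_mask, "nuclei_gt_mask")
  a <- as_mask(artifact_mask, "artifact_mask")
  check_same_shape(p, g, "masks"); check_same_shape(p, a, "masks")

  region_masks <- list(inside_artifacts = a == 1L,
                       outside_artifacts = a == 0L,
                       all = matrix(TRUE, nrow(a), ncol(a)))
  p_lab <- label_components(p, connectivity)
  g_lab <- label_components(g, connectivity)
  assign_region <- function(lab) {
    n <- max(lab)
    if (n == 0) return(logical(0))
    inside_frac <- vapply(seq_len(n), function(i) {
      px <- lab == i
      sum(px & region_masks$inside_artifacts) / sum(px)
    }, numeric(1))
    inside_frac >= 0.5                               # ties to inside
  }
  p_inside <- assign_region(p_lab)
  g_inside <- assign_region(g_lab)

  lapply(names(region_masks), function(rn) NULL) -> out
  names(out) <- names(region_masks)
  for (rn in names(region_masks)) {
    rm_ <- region_masks[[rn]]
    empty <- !any(rm_)
    pr <- metrics_from_counts(sum(p == 1L & g == 1L & rm_),
                              sum(p == 1L & g == 0L & rm_),
                              sum(p == 0L & g == 1L & rm_),
                              sum(p == 0L & g == 0L & rm_),
                              "pixel", sum(rm_))
    keep_obj <- switch(rn,
                       inside_artifacts = list(p_inside, g_inside),
                       outside_artifacts = list(!p_inside, !g_inside),
                       all = list(rep(TRUE, max(p_lab)),
                                  rep(TRUE, max(g_lab))))
    pl <- p_lab; pl[!(pl %in% which(keep_obj[[1]]))] <- 0L
    gl <- g_lab; gl[!(gl %in% which(keep_obj[[2]]))] <- 0L
    or_ <- object_f1_from_labels(relabel_seq(pl), relabel_seq(gl))
    out[[rn]] <- list(region = rn, pixel_report = pr, object_report = or_,
                      empty_region = empty, n_pixels = sum(rm_))
  }
  out
}

relabel_seq <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) == 0) return(lab)
  map <- integer(max(u)); map[u] <- seq_along(u)
  pos <- lab > 0L
  lab[pos] <- map[lab[pos]]
  lab
}

#' Nucleus morphometry: area and solidity
#'
#' Solidity is object area divided by the area of the convex hull of its
#' pixel set, where each pixel is treated as a unit square and the hull
#' area is the exact (shoelace) area of the hull polygon of all pixel
#' corners. Convex objects therefore have solidity exactly 1.
#'
#' @param nuclei_label_mask integer-labeled matrix (0 = background).
#' @return data.frame with columns `object_id`, `area`, `solidity`.
#' @export
morphometry <- function(nuclei_label_mask) {
  lab <- nuclei_label_mask
  stop_if_not(is.matrix(lab), "label mask must be a matrix")
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0)
    return(data.frame(object_id = integer(0), area = numeric(0),
                      solidity = numeric(0)))
  rows <- lapply(ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    area <- nrow(px)
    hull_area <- convex_hull_pixel_area(px)
    data.frame(object_id = id, area = area,
               solidity = min(1, area / hull_area))
  })
  do.call(rbind, rows)
}

# Convex hull area of a pixel set: hull of the 4 corners of every pixel
# (so single pixels and lines get positive area), exact polygon area by
# the shoelace formula.
convex_hull_pixel_area <- function(px) {
  pts <- rbind(cbind(px[, 1] - 0.5, px[, 2] - 0.5),
               cbind(px[, 1] - 0.5, px[, 2] + 0.5),
               cbind(px[, 1] + 0.5, px[, 2] - 0.5),
               cbind(px[, 1] + 0.5, px[, 2] + 0.5))
  h <- grDevices::chull(pts)
  poly <- pts[h, , drop = FALSE]
  shoelace_area(poly)
}

shoelace_area <- function(poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  abs(sum(poly[j, 1] * poly[, 2] - poly[, 1] * poly[j, 2])) / 2
}

#' Per-well artifact-excluded specific fluorescence intensity
#'
#' Per image: mean fluorescence over cell-and-not-artifact pixels minus
#' mean over background (non-cell, non-artifact) pixels. Per well: the
#' per-image values averaged.
#'
#' @param records list of per-image records, each with `well`, `ligand`,
#'   `concentration`, `fluor`, `cell_mask` and optionally `artifact_mask`
#'   (e.g. the `images` element of [generate_plate()]).
#' @param use_artifact_masks if `FALSE`, artifact masks are ignored
#'   ("no removal"); if a list of masks, those are used instead of the
#'   stored ones (e.g. model predictions).
#' @return data.frame with one row per well: `well`, `ligand`,
#'   `concentration_M`, `specific_intensity`, `mean_cell_intensity`,
#'   `mean_background_intensity`, `n_images_averaged`, `flagged` (wells
#'   with zero usable cell pixels in any image).
#' @export
well_specific_intensity <- function(records, use_artifact_masks = TRUE) {
  stop_if_not(length(records) >= 1, "need at least one image record")
  per_image <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    am <- if (isFALSE(use_artifact_masks)) {
      matrix(0L, nrow(rec$fluor), ncol(rec$fluor))
    } else if (is.list(use_artifact_masks)) {
      as_mask(use_artifact_masks[[i]], "artifact mask")
    } else {
      if (is.null(rec$artifact_mask))
        matrix(0L, nrow(rec$fluor), ncol(rec$fluor))
      else as_mask(rec$artifact_mask, "artifact mask")
    }
    cm <- as_mask(rec$cell_mask, "cell_mask")
    cell_px <- cm == 1L & am == 0L
    bg_px <- cm == 0L & am == 0L
    data.frame(well = rec$well, ligand = rec$ligand,
               concentration_M = rec$concentration,
               cell = if (any(cell_px)) mean(rec$fluor[cell_px]) else NA_real_,
               bg = if (any(bg_px)) mean(rec$fluor[bg_px]) else NA_real_)
  })
  pi_df <- do.call(rbind, per_image)
  out <- lapply(split(pi_df, pi_df$well), function(d) {
    flagged <- anyNA(d$cell) || anyNA(d$bg)
    data.frame(well = d$well[1], ligand = d$ligand[1],
               concentration_M = d$concentration_M[1],
               mean_cell_intensity = mean(d$cell),
               mean_background_intensity = mean(d$bg),
               specific_intensity = mean(d$cell) - mean(d$bg),
               n_images_averaged = nrow(d), flagged = flagged)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$well), ]
}

#' Hill-equation concentration-response fit (slope fixed at -1)
#'
#' Least-squares fit of `Y = Bottom + (Top - Bottom) / (1 + 10^(X -
#' LogIC50))` with `X = log10(concentration)` (the "log(inhibitor) vs.
#' response" model), via Levenberg-Marquardt. Start values: Top/Bottom
#' from the response extremes, LogIC50 from the concentration nearest the
#' midpoint response. The LogIC50 standard deviation is the asymptotic
#' (covariance-based) estimate.
#'
#' @param concentrations molar concentrations (> 0, >= 4 distinct values).
#' @param responses specific intensities, aligned with `concentrations`.
#' @return a `hill_fit` with `logIC50`, `top`, `bottom`, `sd_logIC50`,
#'   `r2`, `residuals`, `fitted`, and the underlying `nls` fit.
#' @export
fit_hill <- function(concentrations, responses) {
  stop_if_not(length(concentrations) == length(responses),
              "concentrations and responses must align")
  stop_if_not(all(concentrations > 0), "concentrations must be positive")
  stop_if_not(length(unique(concentrations)) >= 4,
              "need >= 4 distinct concentrations")
  X <- log10(concentrations)
  top0 <- max(responses); bot0 <- min(responses)
  mid <- (top0 + bot0) / 2
  lg0 <- X[which.min(abs(responses - mid))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      responses ~ bottom + (top - bottom) / (1 + 10^(X - logIC50)),
      start = list(top = top0, bottom = bot0, logIC50 = lg0),
      lower = c(top = -Inf, bottom = -Inf, logIC50 = min(X) - 3),
      upper = c(top = Inf, bottom = Inf, logIC50 = max(X) + 3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Hill fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  co <- stats::coef(fit)
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((responses - mean(responses))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  sds <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) rep(NA_real_, 3))
  structure(list(logIC50 = unname(co["logIC50"]), top = unname(co["top"]),
                 bottom = unname(co["bottom"]),
                 sd_logIC50 = unname(sds["logIC50"]), r2 = r2,
                 residuals = res, fitted = stats::fitted(fit),
                 n = length(responses), fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (slope -1): LogIC50 = %.3f +/- %.3f, Top = %.1f, Bottom = %.1f, R2 = %.4f\n",
              x$logIC50, x$sd_logIC50, x$top, x$bottom, x$r2))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(logIC50 = object$logIC50, top = object$top, bottom = object$bottom)
}

#' @export
predict.hill_fit <- function(object, concentrations, ...) {
  hill_response(object$logIC50, object$top, object$bottom, concentrations)
}

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' Compare two artifact-removal strategies on the same plate
#'
#' @param reference list with `wells` (output of
#'   [well_specific_intensity()]) and `fits` (named list of `hill_fit`,
#'   one per curve/ligand).
#' @param alternative same structure, same wells and curves.
#' @return list with `mean_abs_dlogIC50`, per-curve `dlogIC50`, `pearson_r`
#'   of paired well specific intensities, and per-curve `r2` pairs.
#' @export
compare_removal <- function(reference, alternative) {
  stop_if_not(identical(reference$wells$well, alternative$wells$well),
              "reference and alternative must cover the same wells")
  stop_if_not(identical(sort(names(reference$fits)),
                        sort(names(alternative$fits))),
              "reference and alternative must have the same curves")
  dl <- vapply(names(reference$fits), function(nm) {
    abs(reference$fits[[nm]]$logIC50 - alternative$fits[[nm]]$logIC50)
  }, numeric(1))
  r <- stats::cor(reference$wells$specific_intensity,
                  alternative$wells$specific_intensity)
  r2 <- data.frame(curve = names(reference$fits),
                   r2_reference = vapply(reference$fits, `[[`, numeric(1), "r2"),
                   r2_alternative = vapply(alternative$fits, `[[`,
                                           numeric(1), "r2"))
  rownames(r2) <- NULL
  list(mean_abs_dlogIC50 = mean(dl), dlogIC50 = dl, pearson_r = r,
       r2_pairs = r2)
}
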