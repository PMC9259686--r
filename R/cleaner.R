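# Clean-image synthesis: estimate a 2-D second-order polynomial background,
# build a zero-centered noise profile from background pixels, and replace
# annotated artifact pixels with background + resampled noise. This is how
# reference "clean" counterparts are produced for images where nearly every
# field contains an artifact.

poly_design <- function(h, w, rows, cols) {
  # coordinates normalized to [-1, 1] for conditioning
  x <- if (w > 1) (cols - 1) / (w - 1) * 2 - 1 else rep(0, length(cols))
  y <- if (h > 1) (rows - 1) / (h - 1) * 2 - 1 else rep(0, length(rows))
  cbind(1, x, y, x^2, x * y, y^2)
}

#' Fit a 2-D second-order polynomial background surface
#'
#' Least-squares fit of `b(x, y) = c0 + c1 x + c2 y + c3 x^2 + c4 x y +
#' c5 y^2` to the image intensities, on pixel coordinates normalized to
#' \[-1, 1\]. Pixels under `exclude_mask` (typically annotated artifacts)
#' are excluded from the fit.
#'
#' @param image numeric matrix.
#' @param exclude_mask optional binary matrix; 1 = exclude from the fit.
#' @return a `background_model` with `coeffs` (6 values), `fit_domain`
#'   (image dim) and `coordinate_scaling = "[-1,1]"`.
#' @export
fit_background <- function(image, exclude_mask = NULL) {
  stop_if_not(is.matrix(image), "image must be a matrix")
  h <- nrow(image); w <- ncol(image)
  keep <- if (is.null(exclude_mask)) {
    rep(TRUE, h * w)
  } else {
    check_same_shape(image, exclude_mask, "image and exclude_mask")
    as.vector(as_mask(exclude_mask, "exclude_mask") == 0L)
  }
  stop_if_not(sum(keep) >= 6, "need at least 6 usable pixels for the fit")
  rows <- rep(seq_len(h), times = w)[keep]
  cols <- rep(seq_len(w), each = h)[keep]
  X <- poly_design(h, w, rows, cols)
  fit <- stats::lm.fit(X, as.vector(image)[keep])
  if (fit$rank < 6 || anyNA(fit$coefficients))
    stop("degenerate background fit: rank-deficient design", call. = FALSE)
  structure(list(coeffs = unname(fit$coefficients),
                 fit_domain = c(h, w), coordinate_scaling = "[-1,1]"),
            class = "background_model")
}

#' Evaluate a fitted background surface over its full domain
#'
#' @param model a `background_model`.
#' @return numeric matrix of the model's `fit_domain` size.
#' @export
eval_background <- function(model) {
  h <- model$fit_domain[1]; w <- model$fit_domain[2]
  X <- poly_design(h, w, rep(seq_len(h), times = w), rep(seq_len(w), each = h))
  matrix(X %*% model$coeffs, h, w)
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("2-D second-order polynomial background, %dx%d domain\n",
              x$fit_domain[1], x$fit_domain[2]))
  cat("  coeffs (1, x, y, x^2, xy, y^2):",
      paste(signif(x$coeffs, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Zero-centered noise profile of the background pixels
#'
#' Residuals of the image against the fitted background, restricted to the
#' supplied background pixels, then mean-centered.
#'
#' @param image numeric matrix.
#' @param background a `background_model`.
#' @param background_mask binary matrix; 1 = background pixel (>= 100
#'   pixels required).
#' @return a `noise_profile` with mean-centered `residuals` and
#'   `summary_sd`.
#' @export
estimate_noise_profile <- function(image, background, background_mask) {
  check_same_shape(image, background_mask, "image and background_mask")
  sel <- as_mask(background_mask, "background_mask") == 1L
  stop_if_not(sum(sel) >= 100, "need >= 100 background pixels")
  res <- (image - eval_background(background))[sel]
  res <- res - mean(res)
  structure(list(residuals = res, summary_sd = stats::sd(res)),
            class = "noise_profile")
}

#' Inpaint artifact regions with background plus resampled noise
#'
#' Pixels outside the mask are returned unchanged. Pixels inside the mask
#' become the polynomial background value at that pixel plus a draw (with
#' replacement) from the mean-centered empirical noise pool, which
#' preserves non-Gaussian tails. Deterministic given `seed`.
#'
#' @param image numeric matrix.
#' @param artifact_mask binary matrix, aligned with `image`.
#' @param background a `background_model`.
#' @param noise a `noise_profile`.
#' @param seed integer seed for the resampling.
#' @return numeric matrix: the clean image.
#' @export
inpaint <- function(image, artifact_mask, background, noise, seed = 1L) {
  check_same_shape(image, artifact_mask, "image and artifact_mask")
  m <- as_mask(artifact_mask, "artifact_mask") == 1L
  n_in <- sum(m)
  if (n_in == 0) return(image)
  bg <- eval_background(background)
  out <- image
  draws <- with_seed(seed,
                     sample(noise$residuals, n_in, replace = TRUE))
  out[m] <- bg[m] + draws
  out
}

#' One-call clean-image synthesis
#'
#' Fits the background excluding artifact pixels, estimates the noise
#' profile on non-artifact (and, when given, non-nucleus) pixels, and
#' inpaints the artifact region.
#'
#' @param image numeric matrix.
#' @param artifact_mask binary matrix of annotated artifacts.
#' @param nuclei_mask optional binary matrix of nuclei/cell pixels to keep
#'   out of the noise pool.
#' @param seed integer seed.
#' @return list with `clean` (matrix), `background` and `noise`.
#' @export
synthesize_clean <- function(image, artifact_mask, nuclei_mask = NULL,
                             seed = 1L) {
  bgm <- fit_background(image, artifact_mask)
  bg_sel <- as_mask(artifact_mask) == 0L
  if (!is.null(nuclei_mask)) bg_sel <- bg_sel & as_mask(nuclei_mask, "nuclei_mask") == 0L
  npf <- estimate_noise_profile(image, bgm, matrix(as.integer(bg_sel),
                                                   nrow(image), ncol(image)))
  list(clean = inpaint(image, artifact_mask, bgm, npf, seed),
       background = bgm, noise = npf)
}
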