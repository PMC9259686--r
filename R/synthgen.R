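# Synthetic brightfield-like data with exact ground truth.
#
# A field is a smooth second-order polynomial illumination surface plus
# nuclei (soft-edged dark disks), plus zero or more artifacts with distinct
# texture, plus i.i.d. Gaussian noise. Artifact shapes span the
# heterogeneity seen in real screens: filled ellipses with speckle, thin
# fibre/hair curves (dilated random walks), and clumps (unions of
# overlapping disks). Intensities are floating point on a 16-bit-like
# scale; ground-truth masks accompany every image.

#' Specification of one synthetic field of view
#'
#' @param height,width image size in pixels (>= 32).
#' @param background_poly_coeffs 6 coefficients (constant, x, y, x^2, x*y,
#'   y^2) of the illumination surface on coordinates normalized to
#'   \[-1, 1\]; `x` runs along columns, `y` along rows.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (intensity units).
#' @param nucleus_count number of nuclei to draw.
#' @param nucleus_radius_range radius interval in pixels.
#' @param artifact_specs list of [artifact_spec()] objects (possibly empty).
#' @param seed integer seed; equal specs generate bit-identical fields.
#' @return a `field_spec` list.
#' @export
field_spec <- function(height = 96L, width = 96L,
                       background_poly_coeffs = c(30000, 2000, -1500, -800,
                                                  500, -600),
                       noise_sd = 300, nucleus_count = 12L,
                       nucleus_radius_range = c(4, 7),
                       artifact_specs = list(), seed = 1L) {
  stop_if_not(height >= 32 && width >= 32, "height and width must be >= 32")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  stop_if_not(length(background_poly_coeffs) == 6,
              "background_poly_coeffs must have 6 elements")
  stop_if_not(nucleus_count >= 0, "nucleus_count must be >= 0")
  stop_if_not(all(nucleus_radius_range > 0) &&
                nucleus_radius_range[1] <= nucleus_radius_range[2],
              "nucleus_radius_range must be a positive interval")
  structure(list(height = as.integer(height), width = as.integer(width),
                 background_poly_coeffs = as.numeric(background_poly_coeffs),
                 noise_sd = noise_sd, nucleus_count = as.integer(nucleus_count),
                 nucleus_radius_range = nucleus_radius_range,
                 artifact_specs = artifact_specs, seed = as.integer(seed)),
            class = "field_spec")
}

#' Specification of one injected artifact
#'
#' @param shape `"ellipse"` (filled, speckled), `"fiber"` (dilated
#'   random-walk curve) or `"clump"` (union of overlapping disks).
#' @param size_params shape-specific sizes in pixels: ellipse
#'   `c(semi_axis_a, semi_axis_b)`; fiber `c(length_steps, width)`; clump
#'   `c(n_disks, disk_radius)`.
#' @param texture_contrast signed intensity offset relative to the local
#'   background (intensity units; negative = darker).
#' @param position `c(row, col)` center, or `"random"`.
#' @return an `artifact_spec` list.
#' @export
artifact_spec <- function(shape = c("ellipse", "fiber", "clump"),
                          size_params = NULL, texture_contrast = -8000,
                          position = "random") {
  shape <- match.arg(shape)
  if (is.null(size_params))
    size_params <- switch(shape, ellipse = c(14, 8), fiber = c(60, 3),
                          clump = c(6, 7))
  stop_if_not(all(size_params > 0), "size_params must be positive")
  structure(list(shape = shape, size_params = size_params,
                 texture_contrast = texture_contrast, position = position),
            class = "artifact_spec")
}

poly_surface <- function(h, w, coeffs) {
  xs <- if (w > 1) seq(-1, 1, length.out = w) else 0
  ys <- if (h > 1) seq(-1, 1, length.out = h) else 0
  X <- matrix(xs, h, w, byrow = TRUE)
  Y <- matrix(ys, h, w)
  coeffs[1] + coeffs[2] * X + coeffs[3] * Y + coeffs[4] * X^2 +
    coeffs[5] * X * Y + coeffs[6] * Y^2
}

# Filled ellipse mask: pixel centers (row r, col c) with
# ((c-c0)/a)^2 + ((r-r0)/b)^2 <= 1.
ellipse_mask <- function(h, w, center, a, b) {
  R <- matrix(seq_len(h), h, w)
  C <- matrix(seq_len(w), h, w, byrow = TRUE)
  m <- ((C - center[2]) / a)^2 + ((R - center[1]) / b)^2 <= 1
  matrix(as.integer(m), h, w)
}

disk_mask <- function(h, w, center, radius) {
  ellipse_mask(h, w, center, radius, radius)
}

# Dilate a binary mask with a (2r+1)-square structuring element (Chebyshev
# ball), by shifting and OR-ing.
dilate_square <- function(mask, r) {
  if (r <= 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  for (dy in -r:r) for (dx in -r:r) {
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    out[ys, xs] <- pmax(out[ys, xs],
                        mask[ys - dy, xs - dx, drop = FALSE])
  }
  out
}

fiber_mask <- function(h, w, start, n_steps, width) {
  pos <- start
  ang <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(0L, h, w)
  for (i in seq_len(n_steps)) {
    r <- max(1L, min(h, round(pos[1])))
    c <- max(1L, min(w, round(pos[2])))
    pts[r, c] <- 1L
    ang <- ang + stats::rnorm(1, 0, 0.3)
    pos <- pos + c(sin(ang), cos(ang))
    pos[1] <- min(max(pos[1], 1), h)
    pos[2] <- min(max(pos[2], 1), w)
  }
  dilate_square(pts, max(0L, as.integer(floor(width / 2))))
}

clump_mask <- function(h, w, center, n_disks, radius) {
  m <- matrix(0L, h, w)
  for (i in seq_len(n_disks)) {
    ctr <- center + stats::rnorm(2, 0, radius)
    ctr[1] <- min(max(ctr[1], 1), h)
    ctr[2] <- min(max(ctr[2], 1), w)
    m <- pmax(m, disk_mask(h, w, ctr, radius))
  }
  m
}

rasterize_artifact <- function(aspec, h, w) {
  pos <- aspec$position
  if (identical(pos, "random"))
    pos <- c(stats::runif(1, h * 0.15, h * 0.85),
             stats::runif(1, w * 0.15, w * 0.85))
  sp <- aspec$size_params
  m <- switch(aspec$shape,
    ellipse = ellipse_mask(h, w, pos, sp[1], sp[2]),
    fiber = fiber_mask(h, w, pos, as.integer(sp[1]), sp[2]),
    clump = clump_mask(h, w, pos, as.integer(sp[1]), sp[2]))
  if (sum(m) < 1) {                                  # degenerate raster: keep >= 1 px
    m[max(1, min(h, round(pos[1]))), max(1, min(w, round(pos[2])))] <- 1L
  }
  m
}

render_nuclei <- function(h, w, count, radius_range, contrast = -6000) {
  label <- matrix(0L, h, w)
  intensity <- matrix(0, h, w)
  R <- matrix(seq_len(h), h, w)
  C <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(count)) {
    r0 <- stats::runif(1, 0.1 * h, 0.9 * h)
    c0 <- stats::runif(1, 0.1 * w, 0.9 * w)
    rad <- stats::runif(1, radius_range[1], radius_range[2])
    d2 <- (R - r0)^2 + (C - c0)^2
    core <- d2 <= rad^2
    # soft edge: smooth fall-off over ~1.5 px beyond the core
    soft <- exp(-pmax(sqrt(d2) - rad, 0)^2 / (2 * 0.75^2))
    intensity <- intensity + contrast * soft
    label[core & label == 0L] <- i
  }
  list(label = label, intensity = intensity)
}

#' Generate one synthetic field with ground truth
#'
#' Deterministic given the spec (including its seed). The image is the
#' polynomial background plus nuclei, plus artifact textures (intensity
#' offset and, for ellipses/clumps, high-frequency speckle) inside the
#' artifact mask, plus Gaussian noise.
#'
#' @param spec a [field_spec()].
#' @return a `synthetic_field`: list with `image`, `artifact_mask`,
#'   `nuclei_label_mask`, `clean_image` (the artifact-free, noise-included
#'   render), `label` (`"clean"`/`"artifact"`), and the `spec`.
#' @export
generate_field <- function(spec) {
  stop_if_not(inherits(spec, "field_spec"), "spec must be a field_spec")
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    bg <- poly_surface(h, w, spec$background_poly_coeffs)
    nuc <- render_nuclei(h, w, spec$nucleus_count, spec$nucleus_radius_range)
    noise <- matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    base <- bg + nuc$intensity
    amask <- matrix(0L, h, w)
    art_tex <- matrix(0, h, w)
    for (aspec in spec$artifact_specs) {
      m <- rasterize_artifact(aspec, h, w)
      tex <- aspec$texture_contrast
      speck <- if (aspec$shape %in% c("ellipse", "clump")) {
        matrix(stats::rnorm(h * w, 0, abs(tex) * 0.35), h, w)
      } else matrix(0, h, w)
      art_tex <- art_tex * (1 - m) + (tex + speck) * m
      amask <- pmax(amask, m)
    }
    img <- base + art_tex * (amask == 1L) + noise
    structure(list(image = img,
                   clean_image = base + noise,
                   artifact_mask = amask,
                   nuclei_label_mask = nuc$label,
                   label = if (sum(amask) > 0) "artifact" else "clean",
                   spec = spec),
              class = "synthetic_field")
  })
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("synthetic field %dx%d, label = %s, %d artifact px, %d nuclei\n",
              nrow(x$image), ncol(x$image), x$label, sum(x$artifact_mask),
              max(x$nuclei_label_mask)))
  invisible(x)
}

default_artifact_pool <- function() {
  list(
    function() artifact_spec("ellipse",
                             size_params = c(stats::runif(1, 10, 18),
                                             stats::runif(1, 6, 12)),
                             texture_contrast = sample(c(-1, 1), 1) *
                               stats::runif(1, 7000, 12000)),
    function() artifact_spec("fiber",
                             size_params = c(round(stats::runif(1, 50, 90)),
                                             sample(2:5, 1)),
                             texture_contrast = -stats::runif(1, 8000, 12000)),
    function() artifact_spec("clump",
                             size_params = c(sample(4:8, 1),
                                             stats::runif(1, 5, 8)),
                             texture_contrast = sample(c(-1, 1), 1) *
                               stats::runif(1, 7000, 12000))
  )
}

#' Generate a labeled dataset with train/val/test split
#'
#' Exactly `round(n_images * artifact_fraction)` images carry artifacts
#' (1-2 randomly drawn shapes each); the rest are clean. Per-image seeds are
#' derived deterministically from `seed`. Splits are disjoint and
#' exhaustive, with sizes `round(n * ratio)` (the last split absorbs
#' rounding).
#'
#' @param n_images total number of images (>= 5).
#' @param artifact_fraction fraction of images with artifacts, in \[0, 1\].
#' @param field_template a [field_spec()] supplying size, background, noise
#'   and nuclei settings.
#' @param split_ratios three fractions (train, val, test) summing to 1.
#' @param seed master seed.
#' @return an `artseg_dataset`: list of `fields` (synthetic_field objects),
#'   `labels`, and `split` (factor with levels train/val/test).
#' @export
generate_dataset <- function(n_images, artifact_fraction, field_template,
                             split_ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  stop_if_not(n_images >= 5, "n_images must be >= 5")
  stop_if_not(artifact_fraction >= 0 && artifact_fraction <= 1,
              "artifact_fraction must lie in [0, 1]")
  stop_if_not(length(split_ratios) == 3 &&
                abs(sum(split_ratios) - 1) < 1e-6,
              "split_ratios must be three fractions summing to 1")
  n_art <- round(n_images * artifact_fraction)
  pool <- default_artifact_pool()
  fields <- with_seed(seed, {
    is_art <- sample(rep(c(TRUE, FALSE), c(n_art, n_images - n_art)))
    lapply(seq_len(n_images), function(i) {
      sp <- field_template
      sp$seed <- derive_seed(seed, i)
      sp$artifact_specs <- if (is_art[i]) {
        with_seed(derive_seed(seed, n_images + i), {
          k <- sample(1:2, 1)
          lapply(sample(seq_along(pool), k, replace = TRUE),
                 function(j) pool[[j]]())
        })
      } else list()
      generate_field(sp)
    })
  })
  labels <- vapply(fields, `[[`, character(1), "label")
  n_tr <- round(n_images * split_ratios[1])
  n_va <- round(n_images * split_ratios[2])
  n_te <- n_images - n_tr - n_va
  split <- with_seed(derive_seed(seed, 7L),
                     sample(rep(c("train", "val", "test"),
                                c(n_tr, n_va, n_te))))
  structure(list(fields = fields, labels = labels,
                 split = factor(split, levels = c("train", "val", "test"))),
            class = "artseg_dataset")
}

#' Assay specification for a synthetic concentration-response plate
#'
#' @param logIC50_true true log10 molar IC50 of the competitive ligand.
#' @param top,bottom asymptotic specific fluorescence intensities
#'   (`top > bottom`; top = no displacement).
#' @param concentrations molar concentrations tested (all > 0).
#' @param replicates_per_concentration wells per concentration (>= 1;
#'   default 2, i.e. duplicates).
#' @param fields_per_well images per well.
#' @param artifact_rate fraction of images that receive an artifact.
#' @param noise_sd fluorescence noise standard deviation.
#' @param seed integer seed.
#' @return an `assay_spec` list.
#' @export
assay_spec <- function(logIC50_true = -7, top = 1000, bottom = 100,
                       concentrations = 10^seq(-9.5, -4, length.out = 8),
                       replicates_per_concentration = 2L,
                       fields_per_well = 2L, artifact_rate = 0,
                       noise_sd = 0, seed = 1L) {
  stop_if_not(top > bottom, "top must exceed bottom")
  stop_if_not(all(concentrations > 0), "concentrations must be positive")
  stop_if_not(replicates_per_concentration >= 1, "replicates must be >= 1")
  stop_if_not(artifact_rate >= 0 && artifact_rate <= 1,
              "artifact_rate must lie in [0, 1]")
  structure(list(logIC50_true = logIC50_true, top = top, bottom = bottom,
                 concentrations = as.numeric(concentrations),
                 replicates_per_concentration =
                   as.integer(replicates_per_concentration),
                 fields_per_well = as.integer(fields_per_well),
                 artifact_rate = artifact_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "assay_spec")
}

hill_response <- function(logIC50, top, bottom, conc) {
  bottom + (top - bottom) / (1 + 10^(log10(conc) - logIC50))
}

#' Generate a synthetic concentration-response plate
#'
#' Each well holds `fields_per_well` images. The fluorescence channel is a
#' flat background level plus, inside cell pixels, the Hill-curve specific
#' intensity for the well's concentration (slope -1), plus optional noise.
#' Artifacts, injected per image with probability `artifact_rate`, add a
#' strong aberrant fluorescence offset inside their pixels; ground-truth
#' artifact masks are stored so downstream analyses can be compared with
#' and without removal.
#'
#' @param assay an [assay_spec()].
#' @param field_template a [field_spec()] controlling image geometry and
#'   cell (nucleus) layout.
#' @return an `artseg_plate`: list of per-image records (`well`,
#'   `concentration`, `replicate`, `fluor`, `cell_mask`, `artifact_mask`,
#'   `fluor_clean`) plus a `wells` data.frame.
#' @export
generate_plate <- function(assay, field_template = field_spec()) {
  stop_if_not(inherits(assay, "assay_spec"), "assay must be an assay_spec")
  bg_fluor <- 50
  art_fluor_offset <- 4 * (assay$top - assay$bottom)
  images <- list()
  wells <- data.frame(well = character(0), ligand = character(0),
                      concentration_M = numeric(0), replicate = integer(0))
  widx <- 0L
  for (ci in seq_along(assay$concentrations)) {
    conc <- assay$concentrations[ci]
    signal <- hill_response(assay$logIC50_true, assay$top, assay$bottom, conc)
    for (rep_i in seq_len(assay$replicates_per_concentration)) {
      widx <- widx + 1L
      well_id <- sprintf("W%02d", widx)
      wells <- rbind(wells, data.frame(well = well_id, ligand = "L1",
                                       concentration_M = conc,
                                       replicate = rep_i))
      for (fi in seq_len(assay$fields_per_well)) {
        img_seed <- derive_seed(assay$seed, widx * 97L + fi)
        fld <- with_seed(img_seed, {
          sp <- field_template
          sp$seed <- derive_seed(img_seed, 1L)
          has_art <- stats::runif(1) < assay$artifact_rate
          sp$artifact_specs <- if (has_art) {
            pool <- default_artifact_pool()
            list(pool[[sample(seq_along(pool), 1)]]())
          } else list()
          generate_field(sp)
        })
        cell_mask <- matrix(as.integer(fld$nuclei_label_mask > 0),
                            nrow(fld$nuclei_label_mask),
                            ncol(fld$nuclei_label_mask))
        fluor_clean <- bg_fluor + signal * cell_mask
        noise <- if (assay$noise_sd > 0) {
          with_seed(derive_seed(img_seed, 2L),
                    matrix(stats::rnorm(length(fluor_clean), 0,
                                        assay$noise_sd),
                           nrow(fluor_clean), ncol(fluor_clean)))
        } else 0
        fluor <- fluor_clean + noise +
          art_fluor_offset * (fld$artifact_mask == 1L)
        images[[length(images) + 1L]] <-
          list(well = well_id, ligand = "L1", concentration = conc,
               replicate = rep_i, field = fi,
               image = fld$image, fluor = fluor,
               fluor_clean = fluor_clean + noise,
               cell_mask = cell_mask,
               artifact_mask = fld$artifact_mask)
      }
    }
  }
  structure(list(images = images, wells = wells, assay = assay),
            class = "artseg_plate")
}
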