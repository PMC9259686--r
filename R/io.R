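# File interchange: 16-bit TIFF images, 8-bit 0/255 TIFF masks, 32-bit
# float TIFF probability maps, CSV manifests and YAML specs. Intensities
# live on a 16-bit-like [0, 65535] scale in memory and are quantized on
# export.

INTENSITY_MAX <- 65535

#' Write a grayscale intensity image as 16-bit TIFF
#' @param image numeric matrix on a \[0, 65535\] scale.
#' @param path output file.
#' @export
write_image_tiff <- function(image, path) {
  x <- pmin(pmax(image / INTENSITY_MAX, 0), 1)
  tiff::writeTIFF(x, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale TIFF as a \[0, 65535\]-scale matrix
#' @param path input file.
#' @export
read_image_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x * INTENSITY_MAX
}

#' Write a binary mask as 8-bit 0/255 TIFF
#' @param mask binary matrix.
#' @param path output file.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(as_mask(mask) * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask from TIFF/PNG (nonzero = foreground)
#' @param path input file.
#' @export
read_mask <- function(path) {
  x <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(x)) == 3L) x <- x[, , 1]
  matrix(as.integer(x > 0), nrow(x), ncol(x))
}

#' Write a probability/saliency map as 32-bit float TIFF
#' @param map numeric matrix in \[0, 1\].
#' @param path output file.
#' @export
write_map_tiff <- function(map, path) {
  tiff::writeTIFF(pmin(pmax(map, 0), 1), path, bits.per.sample = 32L)
  invisible(path)
}

#' Export a generated dataset to disk
#'
#' Writes per-image 16-bit TIFFs, 8-bit ground-truth masks, a labels
#' manifest CSV (`path`, `label`, `split`, `gt_mask`) and the field
#' template as YAML.
#'
#' @param dataset an `artseg_dataset` from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest data.frame (invisibly).
#' @export
export_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  n <- length(dataset$fields)
  manifest <- data.frame(path = character(n), label = character(n),
                         split = as.character(dataset$split),
                         gt_mask = character(n))
  for (i in seq_len(n)) {
    f <- dataset$fields[[i]]
    ip <- file.path(dir, "images", sprintf("img_%04d.tiff", i))
    mp <- file.path(dir, "masks", sprintf("mask_%04d.tiff", i))
    write_image_tiff(f$image, ip)
    write_mask_tiff(f$artifact_mask, mp)
    manifest$path[i] <- ip
    manifest$label[i] <- f$label
    manifest$gt_mask[i] <- mp
  }
  utils::write.csv(manifest, file.path(dir, "labels.csv"), row.names = FALSE)
  yaml::write_yaml(dataset$fields[[1]]$spec[c("height", "width", "noise_sd",
                                              "nucleus_count")],
                   file.path(dir, "field_template.yaml"))
  invisible(manifest)
}

#' Read a labels manifest CSV
#'
#' Expected columns: `path`, `label` (`clean`/`artifact`); optional
#' `split` and `gt_mask`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if_not(all(c("path", "label") %in% names(m)),
              "manifest needs 'path' and 'label' columns")
  stop_if_not(all(m$label %in% c("clean", "artifact")),
              "labels must be 'clean' or 'artifact'")
  m
}

#' Write a run report as JSON
#' @param report list (e.g. from [run_full_training()]).
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
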