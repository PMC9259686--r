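# Connected-component labeling (4- or 8-connectivity) via union-find, and
# the small-object filter used in post-processing. Implemented in-package
# because the evaluation and post-processing contracts need a selectable
# connectivity.

#' Label connected components of a binary mask
#'
#' Two-pass union-find labeling. Labels are positive integers assigned in
#' raster order; 0 is background.
#'
#' @param mask binary matrix.
#' @param connectivity 4 (edge neighbours) or 8 (edge + diagonal).
#' @return integer matrix of component labels.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- as_mask(mask)
  stop_if_not(connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nxt <- 0L
  for (c in seq_len(w)) for (r in seq_len(h)) {
    if (m[r, c] == 0L) next
    nb <- integer(0)
    if (r > 1 && m[r - 1, c] == 1L) nb <- c(nb, lab[r - 1, c])
    if (c > 1 && m[r, c - 1] == 1L) nb <- c(nb, lab[r, c - 1])
    if (connectivity == 8) {
      if (r > 1 && c > 1 && m[r - 1, c - 1] == 1L) nb <- c(nb, lab[r - 1, c - 1])
      if (r < h && c > 1 && m[r + 1, c - 1] == 1L) nb <- c(nb, lab[r + 1, c - 1])
    }
    if (length(nb) == 0) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[r, c] <- nxt
    } else {
      lab[r, c] <- min(nb)
      for (other in nb) union(lab[r, c], other)
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  relabel <- integer(nxt)
  relabel[sort(unique(roots))] <- seq_along(unique(roots))
  pos <- lab > 0L
  lab[pos] <- relabel[roots[lab[pos]]]
  lab
}

#' Remove small connected components from a binary mask
#'
#' Components with strictly fewer than `min_size` pixels are deleted; all
#' others are untouched. This is the published post-processing filter
#' (minimum sizes 1000 / 500 / 500 pixels for the three full-scale dataset
#' presets).
#'
#' @param mask binary matrix.
#' @param min_size minimum component pixel count to keep.
#' @param connectivity 4 or 8 (default 8).
#' @return integer 0/1 matrix.
#' @export
remove_small_objects <- function(mask, min_size, connectivity = 8) {
  stop_if_not(min_size >= 0, "min_size must be >= 0")
  m <- as_mask(mask)
  if (min_size <= 1 || sum(m) == 0) return(m)
  lab <- label_components(m, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  matrix(as.integer(lab %in% keep), nrow(m), ncol(m))
}
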