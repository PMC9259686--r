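#' @keywords internal
#' @useDynLib artseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed from a master seed and an index.
# Kept strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- (as.double(master) %% m) + 1
  for (i in seq_len(2L)) s <- (s * 48271) %% m
  as.integer((s + 104729 * as.double(index)) %% m)
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

as_mask <- function(x, name = "mask") {
  if (is.logical(x)) x <- x * 1L
  stop_if_not(is.matrix(x) || (is.array(x) && length(dim(x)) == 2L),
              sprintf("%s must be a 2-D matrix", name))
  stop_if_not(all(x %in% c(0, 1)), sprintf("%s must be binary (0/1)", name))
  matrix(as.integer(x), nrow(x), ncol(x))
}

check_same_shape <- function(a, b, what = "inputs") {
  stop_if_not(identical(dim(a)[1:2], dim(b)[1:2]),
              sprintf("%s must share the same height and width", what))
}

# Min-max scale a matrix to [0, 1]; a constant input maps to all zeros
# (a constant map carries no localization signal).
minmax01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' Bilinear resize of a 2-D intensity matrix
#'
#' Separable bilinear interpolation with the half-pixel-center convention
#' used by mainstream image libraries: output pixel center `i + 0.5` maps to
#' source coordinate `(i + 0.5) * h_in / h_out`.
#'
#' @param x numeric matrix.
#' @param out_h,out_w target height and width in pixels.
#' @return numeric matrix of dimension `out_h x out_w`.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  stopifnot(is.matrix(x), out_h >= 1, out_w >= 1)
  interp_mat <- function(n_in, n_out) {
    # rows: output positions; cols: input positions
    src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    lo <- floor(src)
    frac <- src - lo
    hi <- pmin(lo + 1, n_in - 1)
    M <- matrix(0, n_out, n_in)
    idx <- seq_len(n_out)
    M[cbind(idx, lo + 1)] <- M[cbind(idx, lo + 1)] + (1 - frac)
    M[cbind(idx, hi + 1)] <- M[cbind(idx, hi + 1)] + frac
    M
  }
  R <- interp_mat(nrow(x), out_h)
  C <- interp_mat(ncol(x), out_w)
  R %*% x %*% t(C)
}

# Reflect-pad a matrix on the bottom/right so both dims become multiples of m.
pad_to_multiple <- function(x, m) {
  h <- nrow(x); w <- ncol(x)
  ph <- (m - h %% m) %% m
  pw <- (m - w %% m) %% m
  if (ph > 0) {
    stop_if_not(ph < h, "image too small to reflect-pad")
    x <- rbind(x, x[seq(h - 1, h - ph), , drop = FALSE])
  }
  if (pw > 0) {
    stop_if_not(pw < w, "image too small to reflect-pad")
    x <- cbind(x, x[, seq(w - 1, w - pw), drop = FALSE])
  }
  list(x = x, orig = c(h, w))
}
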