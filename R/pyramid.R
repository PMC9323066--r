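# Multiresolution decomposition: the single-level transform iterated on the
# base (WS) quadrant, nesting quadrant layouts down to a 3x3 terminus.

#' Maximum decomposition depth for an image size
#'
#' A level is applied while the current base plane is at least 3 x 3 and
#' strictly larger than 3 x 3: a 3 x 3 base is the terminus of the pyramid
#' and is not decomposed further.  Each level ceil-halves both dimensions
#' (the base keeps the even-index grid, which is the larger half when a
#' dimension is odd).
#'
#' @param H,W image height and width, both >= 3.
#' @return number of levels (0 for a 3 x 3 image).
#' @examples
#' max_levels(4, 4)      # 1
#' max_levels(384, 288)  # 7
#' @export
max_levels <- function(H, W) {
  H <- as.integer(H); W <- as.integer(W)
  if (is.na(H) || is.na(W) || H < 3L || W < 3L)
    stop("max_levels needs H >= 3 and W >= 3")
  lev <- 0L
  while (H >= 3L && W >= 3L && (H > 3L || W > 3L)) {
    lev <- lev + 1L
    H <- (H + 1L) %/% 2L
    W <- (W + 1L) %/% 2L
  }
  lev
}

#' Per-level pyramid geometry
#'
#' Records everything the inverse needs to undo a decomposition: original
#' dimensions, channel count, bit depth, level count, and the (height,
#' width) of the plane each level operated on.  Level `l + 1` always
#' operates on level `l`'s base quadrant, whose size is the ceil-half of the
#' previous level's -- recording each level's own dimensions makes the
#' ceil/floor quadrant splits of odd-sized planes nest unambiguously.
#'
#' @param H,W,channels,bit_depth source image geometry.
#' @param levels number of decomposition levels, >= 1.
#' @return object of class `pyramid_spec` with a `level_dims` matrix
#'   (one row per level: the input size at that level).
#' @export
pyramid_spec <- function(H, W, channels, bit_depth, levels) {
  H <- as.integer(H); W <- as.integer(W); levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  dims <- matrix(0L, levels, 2L, dimnames = list(NULL, c("h", "w")))
  h <- H; w <- W
  for (l in seq_len(levels)) {
    if (h < 3L || w < 3L)
      stop(sprintf("level %d would operate on a %d x %d plane (min 3 x 3)", l, h, w))
    dims[l, ] <- c(h, w)
    h <- (h + 1L) %/% 2L
    w <- (w + 1L) %/% 2L
  }
  structure(
    list(height = H, width = W, channels = as.integer(channels),
         bit_depth = as.integer(bit_depth), levels = levels,
         level_dims = dims),
    class = "pyramid_spec")
}

#' @export
print.pyramid_spec <- function(x, ...) {
  cat(sprintf("<pyramid_spec %d x %d x %d, %d-bit, %d level(s); deepest base %d x %d>\n",
              x$height, x$width, x$channels, x$bit_depth, x$levels,
              (x$level_dims[x$levels, 1] + 1L) %/% 2L,
              (x$level_dims[x$levels, 2] + 1L) %/% 2L))
  invisible(x)
}

#' Multiresolution decomposition
#'
#' Applies the single-level transform [forward_2d()] `levels` times, each
#' time to the base quadrant left by the previous level, independently per
#' channel.  The deepest base quadrant holds raw subsampled pixels; every
#' other coefficient is a signed detail residual.
#'
#' @param grid a `pixel_grid` (1 or 3 channels).
#' @param levels number of levels; `"max"` uses `max(1, max_levels(H, W))`.
#' @return list with `coeffs` (a `coeff_grid`) and `spec` (a `pyramid_spec`).
#' @export
decompose <- function(grid, levels = "max") {
  if (!inherits(grid, "pixel_grid")) stop("grid must be a pixel_grid")
  if (identical(levels, "max"))
    levels <- max(1L, max_levels(grid$height, grid$width))
  spec <- pyramid_spec(grid$height, grid$width, grid$channels,
                       grid$bit_depth, levels)
  vals <- grid$samples
  for (l in seq_len(spec$levels)) {
    h <- spec$level_dims[l, 1]; w <- spec$level_dims[l, 2]
    for (ch in seq_len(grid$channels))
      vals[1:h, 1:w, ch] <- fwd2d_mat(vals[1:h, 1:w, ch, drop = TRUE])
  }
  list(coeffs = coeff_grid(vals, bit_depth = grid$bit_depth), spec = spec)
}

#' Multiresolution reconstruction
#'
#' Bit-exact inverse of [decompose()]: undoes the levels deepest-first,
#' re-running the single-level inverse on each nested base quadrant.
#'
#' @param coeffs `coeff_grid` from [decompose()].
#' @param spec matching `pyramid_spec`.
#' @return the original `pixel_grid`, sample-exactly.
#' @export
reconstruct <- function(coeffs, spec) {
  if (!inherits(coeffs, "coeff_grid")) stop("coeffs must be a coeff_grid")
  if (!inherits(spec, "pyramid_spec")) stop("spec must be a pyramid_spec")
  if (coeffs$height != spec$height || coeffs$width != spec$width ||
      coeffs$channels != spec$channels)
    stop("coeffs and spec disagree on geometry")
  vals <- coeffs$values
  for (l in rev(seq_len(spec$levels))) {
    h <- spec$level_dims[l, 1]; w <- spec$level_dims[l, 2]
    for (ch in seq_len(spec$channels))
      vals[1:h, 1:w, ch] <- inv2d_mat(vals[1:h, 1:w, ch, drop = TRUE], h, w)
  }
  pixel_grid(vals, bit_depth = spec$bit_depth)
}
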