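#' @useDynLib difftx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- domain types -----------------------------------------------------------

#' Integer raster container
#'
#' A `pixel_grid` is the codec's lossless unit: an integer raster of
#' `height x width x channels` samples with a declared bit depth.  All
#' transforms in this package consume and produce `pixel_grid` objects (or
#' single-channel planes extracted from them) and round-trip them bit-exactly.
#'
#' @param samples integer matrix (single channel) or H x W x C array with
#'   C in `{1, 3}`; every value must lie in `[0, 2^bit_depth - 1]`.
#' @param bit_depth bits per sample, 8 or 16.
#' @return An object of class `pixel_grid` with fields `height`, `width`,
#'   `channels`, `bit_depth` and `samples` (always stored as an H x W x C
#'   integer array).
#' @examples
#' g <- pixel_grid(matrix(0:15, 4, 4), bit_depth = 8)
#' g$height
#' @export
pixel_grid <- function(samples, bit_depth = 8L) {
  if (is.matrix(samples)) dim(samples) <- c(dim(samples), 1L)
  if (!is.array(samples) || length(dim(samples)) != 3L)
    stop("samples must be a matrix or an H x W x C array")
  d <- dim(samples)
  if (!d[3] %in% c(1L, 3L)) stop("channels must be 1 or 3")
  if (d[1] < 3L || d[2] < 3L)
    stop("pixel_grid needs height >= 3 and width >= 3")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  storage.mode(samples) <- "integer"
  if (anyNA(samples)) stop("samples contain NA")
  maxv <- 2L^as.integer(bit_depth) - 1L
  if (min(samples) < 0L || max(samples) > maxv)
    stop(sprintf("samples out of range [0, %d]", maxv))
  structure(
    list(height = d[1], width = d[2], channels = d[3],
         bit_depth = as.integer(bit_depth), samples = samples),
    class = "pixel_grid")
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid %d x %d, %d channel(s), %d-bit>\n",
              x$height, x$width, x$channels, x$bit_depth))
  invisible(x)
}

#' @export
format.pixel_grid <- function(x, ...) {
  sprintf("%dx%dx%d/%d-bit", x$height, x$width, x$channels, x$bit_depth)
}

#' Test two grids for sample-exact equality
#' @param a,b `pixel_grid` objects.
#' @return `TRUE` iff dimensions, depth and every sample agree.
#' @export
grids_identical <- function(a, b) {
  identical(dim(a$samples), dim(b$samples)) &&
    a$bit_depth == b$bit_depth &&
    all(a$samples == b$samples)
}

#' Transform-coefficient container
#'
#' Holds the signed integer coefficients of a (possibly multi-level)
#' difference-transform decomposition, packed in place: the base (WS)
#' quadrant of size `ceil(H/2) x ceil(W/2)` sits top-left, horizontal (WH)
#' details top-right, vertical (WV) bottom-left and diagonal (WD)
#' bottom-right; deeper levels recurse into the WS block.  The coefficient
#' count always equals the source sample count.
#'
#' @param values signed integer H x W x C array of coefficients.
#' @param bit_depth bit depth of the source image (8 or 16).
#' @return An object of class `coeff_grid`.
#' @export
coeff_grid <- function(values, bit_depth = 8L) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  d <- dim(values)
  storage.mode(values) <- "integer"
  structure(
    list(height = d[1], width = d[2], channels = d[3],
         bit_depth = as.integer(bit_depth), values = values),
    class = "coeff_grid")
}

#' @export
print.coeff_grid <- function(x, ...) {
  cat(sprintf("<coeff_grid %d x %d, %d channel(s), source %d-bit>\n",
              x$height, x$width, x$channels, x$bit_depth))
  invisible(x)
}

#' The shared three-tap difference filter
#'
#' The single filter underlying the transform: taps `(1/2, -1, 1/2)` on
#' support `{-1, 0, 1}`.  The horizontal, vertical and diagonal detail
#' filters all use these values and differ only in the direction along
#' which they are applied.  The taps sum to zero, so constant signals give
#' zero detail, and the filter is symmetric.
#'
#' @return named numeric vector of taps.
#' @export
diff_filter <- function() c(`-1` = 0.5, `0` = -1, `1` = 0.5)

# ---- 1D transform -----------------------------------------------------------

# clamp 0-based even-grid index to the largest even index < L
.clamp_even <- function(i, L) pmin(i, if (L %% 2L == 0L) L - 2L else L - 1L)

#' Forward 1D difference transform
#'
#' Splits an integer sequence into its even-index samples and a residual for
#' each odd-index sample: the floor of its even-neighbor average minus the
#' sample itself.  At the right edge of an even-length sequence the missing
#' even neighbor is replicated from the nearest in-range even index.  The
#' transform is exactly invertible by [inverse_1d()] because the inverse can
#' recompute the identical neighbor average from the retained even samples.
#'
#' @param x integer vector, length >= 3, values in `[0, 2^N - 1]`.
#' @return list with `evens` (length `ceiling(L/2)`) and `details`
#'   (signed, length `floor(L/2)`).
#' @examples
#' forward_1d(c(10L, 12L, 14L, 16L))
#' @export
forward_1d <- function(x) {
  L <- length(x)
  if (L < 3L) stop("sequence length must be >= 3")
  if (anyNA(x) || any(x != as.integer(x)) || any(x < 0))
    stop("values must be non-negative integers")
  x <- as.integer(x)
  evens <- x[seq.int(1L, L, by = 2L)]
  odd0 <- seq.int(1L, L - 1L, by = 2L)          # 0-based odd positions
  if (length(odd0) == 0L) return(list(evens = evens, details = integer(0)))
  left  <- x[odd0]                               # 0-based odd0 - 1, R index odd0
  right <- x[.clamp_even(odd0 + 1L, L) + 1L]
  details <- (left + right) %/% 2L - x[odd0 + 1L]
  list(evens = evens, details = details)
}

#' Inverse 1D difference transform
#'
#' Re-interleaves the even samples and recovers each odd sample as the floor
#' of its even-neighbor average minus its residual, using the same boundary
#' replication as [forward_1d()].  `inverse_1d(forward_1d(x), ...)` is the
#' identity, bit-exactly.
#'
#' @param evens integer vector of retained even-index samples.
#' @param details signed integer vector of odd-position residuals.
#' @param L original sequence length.
#' @return integer vector of length `L`.
#' @export
inverse_1d <- function(evens, details, L) {
  if (length(evens) != ceiling(L / 2) || length(details) != L %/% 2L)
    stop("evens/details lengths inconsistent with L")
  out <- integer(L)
  out[seq.int(1L, L, by = 2L)] <- as.integer(evens)
  if (L >= 2L) {
    odd0 <- seq.int(1L, L - 1L, by = 2L)
    left  <- out[odd0]
    right <- out[.clamp_even(odd0 + 1L, L) + 1L]
    out[odd0 + 1L] <- (left + right) %/% 2L - as.integer(details)
  }
  out
}

# ---- 2D transform (single level), matrix kernels ----------------------------

# even/odd 0-based index vectors as R (1-based) indices
.er <- function(n) seq.int(1L, n, by = 2L)
.or <- function(n) if (n >= 2L) seq.int(2L, n, by = 2L) else integer(0)

# forward single-level transform of an integer matrix; returns the packed
# quadrant matrix [WS WH; WV WD]
fwd2d_mat <- function(m) {
  h <- nrow(m); w <- ncol(m)
  er <- .er(h); or_ <- .or(h)
  ec <- .er(w); oc <- .or(w)
  le <- er[length(er)]; lc <- ec[length(ec)]   # last in-range even row/col
  out <- matrix(0L, h, w)
  ch <- length(er); cw <- length(ec)
  out[1:ch, 1:cw] <- m[er, ec, drop = FALSE]                       # WS
  if (length(oc))                                                  # WH
    out[1:ch, (cw + 1L):w] <-
      (m[er, oc - 1L, drop = FALSE] + m[er, pmin(oc + 1L, lc), drop = FALSE]) %/% 2L -
      m[er, oc, drop = FALSE]
  if (length(or_))                                                 # WV
    out[(ch + 1L):h, 1:cw] <-
      (m[or_ - 1L, ec, drop = FALSE] + m[pmin(or_ + 1L, le), ec, drop = FALSE]) %/% 2L -
      m[or_, ec, drop = FALSE]
  if (length(or_) && length(oc))                                   # WD
    out[(ch + 1L):h, (cw + 1L):w] <-
      (m[or_ - 1L, oc - 1L, drop = FALSE] +
         m[pmin(or_ + 1L, le), pmin(oc + 1L, lc), drop = FALSE]) %/% 2L -
      m[or_, oc, drop = FALSE]
  out
}

# inverse single-level transform; cm is the packed quadrant matrix, (h, w)
# the original plane size.  order: permutation of c("H","V","D") -- the three
# reconstruction passes read only WS samples, so any order gives the same
# result (asserted in the tests).
inv2d_mat <- function(cm, h, w, order = c("H", "V", "D")) {
  stopifnot(nrow(cm) == h, ncol(cm) == w)
  er <- .er(h); or_ <- .or(h)
  ec <- .er(w); oc <- .or(w)
  le <- er[length(er)]; lc <- ec[length(ec)]
  ch <- length(er); cw <- length(ec)
  out <- matrix(0L, h, w)
  out[er, ec] <- cm[1:ch, 1:cw, drop = FALSE]    # oversample: replant WS
  passes <- list(
    H = function() {
      if (length(oc))
        out[er, oc] <<-
          (out[er, oc - 1L, drop = FALSE] + out[er, pmin(oc + 1L, lc), drop = FALSE]) %/% 2L -
          cm[1:ch, (cw + 1L):w, drop = FALSE]
    },
    V = function() {
      if (length(or_))
        out[or_, ec] <<-
          (out[or_ - 1L, ec, drop = FALSE] + out[pmin(or_ + 1L, le), ec, drop = FALSE]) %/% 2L -
          cm[(ch + 1L):h, 1:cw, drop = FALSE]
    },
    D = function() {
      if (length(or_) && length(oc))
        out[or_, oc] <<-
          (out[or_ - 1L, oc - 1L, drop = FALSE] +
             out[pmin(or_ + 1L, le), pmin(oc + 1L, lc), drop = FALSE]) %/% 2L -
          cm[(ch + 1L):h, (cw + 1L):w, drop = FALSE]
    })
  for (p in order) passes[[p]]()
  out
}

# ---- 2D transform, public single-level ops ----------------------------------

#' Forward 2D difference transform (one level)
#'
#' Applies the transform to a single-channel plane, producing four quadrants:
#' `WS(m, n) = f(2m, 2n)` (the subsampled original, top-left), plus
#' horizontal, vertical and diagonal detail planes holding the floored
#' even-neighbor-average residual of each dropped sample.  Horizontal details
#' live at (even row, odd column) positions and predict from the two
#' horizontal even-grid neighbors; vertical details are symmetric; diagonal
#' details at (odd, odd) predict from the `(2m, 2n)` and `(2m+2, 2n+2)`
#' diagonal neighbors.  Out-of-range even neighbors at the far edge of an
#' even-sized dimension are replicated from the nearest in-range even index.
#'
#' @param plane single-channel `pixel_grid` (or an integer matrix plus
#'   `bit_depth`).
#' @param bit_depth used only when `plane` is a bare matrix.
#' @return `coeff_grid` with the four quadrants packed in place.
#' @export
forward_2d <- function(plane, bit_depth = 8L) {
  if (inherits(plane, "pixel_grid")) {
    if (plane$channels != 1L) stop("forward_2d takes a single-channel plane")
    m <- plane$samples[, , 1L]
    bit_depth <- plane$bit_depth
  } else m <- plane
  if (nrow(m) < 3L || ncol(m) < 3L) stop("plane must be at least 3 x 3")
  storage.mode(m) <- "integer"
  coeff_grid(fwd2d_mat(m), bit_depth = bit_depth)
}

#' Inverse 2D difference transform (one level)
#'
#' Bit-exact inverse of [forward_2d()].  Reconstruction replants the WS
#' samples on the even grid, then runs the horizontal, vertical and diagonal
#' passes; each pass reads only WS samples, so the passes commute.
#'
#' @param coeffs `coeff_grid` from [forward_2d()].
#' @param order permutation of `c("H", "V", "D")`; the result is identical
#'   for all six orders.
#' @return single-channel `pixel_grid`.
#' @export
inverse_2d <- function(coeffs, order = c("H", "V", "D")) {
  if (!inherits(coeffs, "coeff_grid")) stop("coeffs must be a coeff_grid")
  if (coeffs$channels != 1L) stop("inverse_2d takes a single-channel coeff_grid")
  if (!setequal(order, c("H", "V", "D")) || length(order) != 3L)
    stop("order must be a permutation of H, V, D")
  m <- inv2d_mat(coeffs$values[, , 1L], coeffs$height, coeffs$width, order)
  pixel_grid(m, bit_depth = coeffs$bit_depth)
}
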