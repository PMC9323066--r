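# Deterministic synthetic rasters: the test battery's stand-in for the
# photographic and medical sets the codec targets.  Every kind is a function
# of (kind, dims, depth, seed) only, so fixture files are byte-reproducible.

FIXTURE_KINDS <- c("constant", "ramp_x", "ramp_y", "ramp_diag",
                   "checkerboard", "uniform_noise", "blob_phantom")

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv()))
  expr
}

#' Generate a synthetic test image
#'
#' Seven deterministic families spanning the compressibility range:
#' `constant` (flat mid-gray, zero detail energy), `ramp_x` / `ramp_y` /
#' `ramp_diag` (locally linear gradients, near-zero details), `checkerboard`
#' (4-pixel blocks at full contrast), `uniform_noise` (i.i.d. uniform
#' samples, incompressible), and `blob_phantom` (a sum of smooth radial
#' bumps on a dark background, emulating X-ray content).
#'
#' @param kind one of `r paste0('"', FIXTURE_KINDS, '"', collapse = ", ")`.
#' @param height,width image size, >= 3.
#' @param channels 1 or 3.
#' @param bit_depth 8 or 16.
#' @param seed RNG seed for the stochastic kinds (also varies blob layout).
#' @return a `pixel_grid`.
#' @export
fixture_grid <- function(kind, height = 64L, width = 64L, channels = 1L,
                         bit_depth = 8L, seed = 1L) {
  kind <- match.arg(kind, FIXTURE_KINDS)
  maxv <- 2L^bit_depth - 1L
  H <- as.integer(height); W <- as.integer(width); C <- as.integer(channels)
  y <- matrix(seq_len(H) - 1L, H, W)
  x <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)
  plane <- switch(kind,
    constant = matrix(maxv %/% 2L, H, W),
    ramp_x = floor(x / max(W - 1L, 1L) * maxv),
    ramp_y = floor(y / max(H - 1L, 1L) * maxv),
    ramp_diag = floor((x + y) / max(H + W - 2L, 1L) * maxv),
    checkerboard = ((x %/% 4L + y %/% 4L) %% 2L) * maxv,
    uniform_noise = NULL,
    blob_phantom = NULL)
  arr <- array(0L, dim = c(H, W, C))
  if (kind == "uniform_noise") {
    arr[] <- with_seed(seed, as.integer(floor(stats::runif(H * W * C) * (maxv + 1L))))
  } else if (kind == "blob_phantom") {
    arr[] <- with_seed(seed, {
      vapply(seq_len(C), function(ch) {
        nb <- sample(3:6, 1L)
        img <- matrix(0.05 * maxv, H, W)
        for (b in seq_len(nb)) {
          cy <- stats::runif(1, 0, H - 1); cx <- stats::runif(1, 0, W - 1)
          sig <- stats::runif(1, 0.08, 0.25) * min(H, W)
          amp <- stats::runif(1, 0.3, 0.9) * maxv
          img <- img + amp * exp(-((y - cy)^2 + (x - cx)^2) / (2 * sig^2))
        }
        as.integer(pmin(round(img), maxv))
      }, integer(H * W))
    })
  } else {
    for (ch in seq_len(C)) arr[, , ch] <- as.integer(plane)
  }
  pixel_grid(arr, bit_depth = bit_depth)
}

#' Write a battery of fixture files
#'
#' Renders fixtures to disk in a chosen raster format; file names encode the
#' generating parameters.  The same call always produces byte-identical
#' files.
#'
#' @param out_dir output directory (created if absent).
#' @param kinds subset of the fixture families.
#' @param height,width,channels,bit_depth,seed passed to [fixture_grid()].
#' @param format output raster format (`"pnm"`, `"png"`, `"tiff"`, `"bmp"`).
#' @return character vector of file paths, invisibly.
#' @export
make_fixtures <- function(out_dir, kinds = FIXTURE_KINDS, height = 64L,
                          width = 64L, channels = 1L, bit_depth = 8L,
                          seed = 1L, format = "pnm") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- switch(format,
                pnm = if (channels == 1L) "pgm" else "ppm",
                png = "png", tiff = "tif", bmp = "bmp",
                stop(sprintf("unsupported fixture format '%s'", format)))
  paths <- vapply(kinds, function(k) {
    g <- fixture_grid(k, height, width, channels, bit_depth, seed)
    p <- file.path(out_dir, sprintf("%s_%dx%d_c%d_d%d_s%d.%s",
                                    k, height, width, channels, bit_depth, seed, ext))
    write_image(g, p, format)
    p
  }, character(1))
  invisible(unname(paths))
}
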