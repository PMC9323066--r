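# Raster I/O: dispatch over PNM / PNG / TIFF / BMP, preserving bit depth and
# channel count.  All readers return an image_record wrapping a pixel_grid;
# all writers return the on-disk byte size (the numerator/denominator unit
# of the benchmark's compression ratio).

# ---- sample <-> byte-stream helpers (row-major, channel-interleaved) --------

decode_interleaved <- function(bytes, H, W, C, depth, endian = "big") {
  if (depth == 8L) {
    v <- as.integer(bytes)
  } else {
    b <- as.integer(bytes)
    odd <- seq.int(1L, length(b), by = 2L)
    v <- if (endian == "big") b[odd] * 256L + b[odd + 1L]
         else b[odd + 1L] * 256L + b[odd]
  }
  if (length(v) != H * W * C) format_error("pixel payload size mismatch")
  aperm(array(v, dim = c(C, W, H)), c(3L, 2L, 1L))
}

encode_interleaved <- function(grid, endian = "big") {
  v <- as.vector(aperm(grid$samples, c(3L, 2L, 1L)))
  if (grid$bit_depth == 8L) return(as.raw(v))
  hi <- as.raw(v %/% 256L); lo <- as.raw(v %% 256L)
  out <- raw(2L * length(v))
  if (endian == "big") {
    out[c(TRUE, FALSE)] <- hi; out[c(FALSE, TRUE)] <- lo
  } else {
    out[c(TRUE, FALSE)] <- lo; out[c(FALSE, TRUE)] <- hi
  }
  out
}

u32be <- function(x) as.raw((x %/% 256^(3:0)) %% 256)
u32le <- function(x) as.raw((x %/% 256^(0:3)) %% 256)
u16le <- function(x) as.raw((x %/% 256^(0:1)) %% 256)
rd_uint <- function(bytes, endian = "little")
  sum(as.numeric(bytes) * 256^(if (endian == "little") seq_along(bytes) - 1
                               else rev(seq_along(bytes) - 1)))

# ---- format detection -------------------------------------------------------

detect_format <- function(path) {
  magic <- readBin(path, "raw", n = 8L)
  if (length(magic) >= 2L && magic[1] == charToRaw("P") &&
      rawToChar(magic[2]) %in% c("2", "3", "5", "6")) return("pnm")
  if (length(magic) >= 8L &&
      identical(magic, as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)))) return("png")
  if (length(magic) >= 4L &&
      (identical(magic[1:4], as.raw(c(0x49, 0x49, 0x2A, 0x00))) ||
       identical(magic[1:4], as.raw(c(0x4D, 0x4D, 0x00, 0x2A))))) return("tiff")
  if (length(magic) >= 2L && identical(magic[1:2], charToRaw("BM"))) return("bmp")
  format_error(sprintf("unsupported or unrecognized image format: %s", path))
}

format_from_ext <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pgm = , ppm = , pnm = "pnm",
         png = "png",
         tif = , tiff = "tiff",
         bmp = "bmp",
         format_error(sprintf("cannot infer image format from extension '.%s'", ext)))
}

# ---- public interface -------------------------------------------------------

#' Read a raster image
#'
#' Decodes PNM (P2/P3/P5/P6), PNG (gray/RGB, 8/16-bit, non-interlaced),
#' TIFF (uncompressed or deflate, contiguous planar) or BMP (24-bit) into a
#' [pixel_grid], preserving bit depth and channel count.  16-bit PNM and
#' PNG samples are big-endian per their standards; TIFF follows its own
#' byte-order header.
#'
#' @param path file path; the format is sniffed from the file's magic bytes.
#' @return object of class `image_record`: `path`, `format`, `bytes` (the
#'   on-disk container size) and `grid` (the decoded `pixel_grid`).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  fmt <- detect_format(path)
  grid <- switch(fmt,
                 pnm = read_pnm(path),
                 png = read_png(path),
                 tiff = read_tiff(path),
                 bmp = read_bmp(path))
  structure(list(path = path, format = fmt,
                 bytes = file.size(path), grid = grid),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record %s [%s, %d bytes]: %s>\n",
              basename(x$path), x$format, x$bytes, format(x$grid)))
  invisible(x)
}

#' Write a raster image
#'
#' Encodes a [pixel_grid] as PNM (binary P5/P6), PNG, TIFF (uncompressed)
#' or BMP (24-bit).  Formats that cannot carry the grid's depth or channel
#' count (e.g. 16-bit BMP) raise a capability error.
#'
#' @param grid `pixel_grid` to write.
#' @param path output path.
#' @param format one of `"pnm"`, `"png"`, `"tiff"`, `"bmp"`; inferred from
#'   the file extension when `NULL`.
#' @return the byte size of the written file, invisibly.
#' @export
write_image <- function(grid, path, format = NULL) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (is.null(format)) format <- format_from_ext(path)
  switch(format,
         pnm = write_pnm(grid, path),
         png = write_png(grid, path),
         tiff = write_tiff(grid, path),
         bmp = write_bmp(grid, path),
         format_error(sprintf("unsupported output format '%s'", format)))
  invisible(file.size(path))
}

#' Compression ratio
#'
#' Original container file size divided by compressed file size.  Values
#' below 1 are legal and meaningful: they occur when the source container
#' is itself already compressed (e.g. PNG or LZW TIFF originals), so the
#' baseline is smaller than the raw raster.
#'
#' @param original_bytes,compressed_bytes positive byte counts.
#' @return the ratio as a double.
#' @export
compression_ratio <- function(original_bytes, compressed_bytes) {
  if (any(original_bytes <= 0) || any(compressed_bytes <= 0))
    stop("byte counts must be positive")
  as.numeric(original_bytes) / as.numeric(compressed_bytes)
}
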