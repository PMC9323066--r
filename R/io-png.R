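# PNG, pure R + compiled CRC/unfilter: grayscale (color type 0) and RGB
# (color type 2) at 8 or 16 bits, non-interlaced.  The IDAT stream is a raw
# zlib stream, which base R's memCompress/memDecompress(type = "gzip")
# produce and consume directly.  Written scanlines use filter type 0; read
# scanlines may use any of the five standard filters.

PNG_SIG <- as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(.crc32(body)))
}

read_png <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 8L || !identical(bytes[1:8], PNG_SIG))
    format_error("not a PNG file")
  pos <- 9L
  ihdr <- NULL
  idat <- list()
  while (pos + 7L <= length(bytes)) {
    len <- rd_uint(bytes[pos:(pos + 3L)], "big")
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    dstart <- pos + 8L
    if (dstart + len + 3L > length(bytes) + 1L)
      corrupt_error(sprintf("truncated PNG chunk '%s' at byte offset %d", type, pos - 1L))
    data <- if (len > 0) bytes[dstart:(dstart + len - 1L)] else raw(0)
    crc <- rd_uint(bytes[(dstart + len):(dstart + len + 3L)], "big")
    if (crc != .crc32(c(bytes[(pos + 4L):(pos + 7L)], data)))
      corrupt_error(sprintf("PNG chunk '%s' CRC mismatch at byte offset %d", type, pos - 1L))
    if (type == "IHDR") ihdr <- data
    else if (type == "IDAT") idat[[length(idat) + 1L]] <- data
    else if (type == "IEND") break
    pos <- dstart + len + 4L
  }
  if (is.null(ihdr) || length(ihdr) != 13L) format_error("PNG missing IHDR")
  W <- rd_uint(ihdr[1:4], "big"); H <- rd_uint(ihdr[5:8], "big")
  depth <- as.integer(ihdr[9]); ctype <- as.integer(ihdr[10])
  interlace <- as.integer(ihdr[13])
  if (!depth %in% c(8L, 16L) || !ctype %in% c(0L, 2L))
    format_error(sprintf("unsupported PNG: bit depth %d, color type %d (need gray/RGB 8/16-bit)",
                         depth, ctype))
  if (interlace != 0L) format_error("interlaced PNG not supported")
  if (length(idat) == 0L) corrupt_error("PNG has no IDAT data")
  C <- if (ctype == 2L) 3L else 1L
  raw_data <- memDecompress(do.call(c, idat), type = "gzip")
  bpp <- C * depth %/% 8L
  rowbytes <- W * bpp
  if (length(raw_data) != H * (rowbytes + 1L))
    corrupt_error("PNG scanline data has unexpected length")
  flat <- .png_unfilter(raw_data, H, rowbytes, bpp)
  pixel_grid(decode_interleaved(flat, H, W, C, depth, "big"), bit_depth = depth)
}

write_png <- function(grid, path) {
  ctype <- if (grid$channels == 3L) 2L else 0L
  ihdr <- c(u32be(grid$width), u32be(grid$height),
            as.raw(c(grid$bit_depth, ctype, 0L, 0L, 0L)))
  flat <- encode_interleaved(grid, "big")
  rowbytes <- grid$width * grid$channels * grid$bit_depth %/% 8L
  rows <- matrix(flat, nrow = rowbytes)
  filtered <- as.vector(rbind(rep(as.raw(0L), grid$height), rows))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(PNG_SIG, con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", memCompress(filtered, type = "gzip")), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}
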