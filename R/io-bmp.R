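# BMP, 24-bit BI_RGB only: bottom-up (or top-down) rows of BGR triples,
# each row padded to a 4-byte boundary.  BMP cannot carry 16-bit samples or
# a true single-channel raster, so anything but an 8-bit 3-channel grid is
# a capability error on write.

read_bmp <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 54L || !identical(bytes[1:2], charToRaw("BM")))
    format_error("not a BMP file")
  data_off <- rd_uint(bytes[11:14], "little")
  hdr_size <- rd_uint(bytes[15:18], "little")
  if (hdr_size < 40L) format_error("unsupported BMP header")
  W <- rd_uint(bytes[19:22], "little")
  Hraw <- rd_uint(bytes[23:26], "little")
  topdown <- Hraw >= 2^31          # negative i32 height = top-down rows
  H <- if (topdown) 2^32 - Hraw else Hraw
  bpp <- rd_uint(bytes[29:30], "little")
  comp <- rd_uint(bytes[31:34], "little")
  if (bpp != 24 || comp != 0)
    format_error(sprintf("unsupported BMP: %g bpp, compression %g (only 24-bit BI_RGB)",
                         bpp, comp))
  stride <- ((W * 3 + 3) %/% 4) * 4
  if (data_off + stride * H > length(bytes))
    corrupt_error("BMP pixel data shorter than header promises")
  arr <- array(0L, dim = c(H, W, 3L))
  rows <- if (topdown) seq_len(H) else rev(seq_len(H))
  for (i in seq_len(H)) {
    r0 <- data_off + (i - 1) * stride
    row <- as.integer(bytes[(r0 + 1L):(r0 + W * 3L)])
    y <- rows[i]
    arr[y, , 3L] <- row[seq(1L, by = 3L, length.out = W)]  # B
    arr[y, , 2L] <- row[seq(2L, by = 3L, length.out = W)]  # G
    arr[y, , 1L] <- row[seq(3L, by = 3L, length.out = W)]  # R
  }
  pixel_grid(arr, bit_depth = 8L)
}

write_bmp <- function(grid, path) {
  if (grid$bit_depth != 8L || grid$channels != 3L)
    format_error(sprintf("BMP cannot carry a %d-bit %d-channel image (24-bit RGB only)",
                         grid$bit_depth, grid$channels))
  W <- grid$width; H <- grid$height
  stride <- ((W * 3L + 3L) %/% 4L) * 4L
  pad <- stride - W * 3L
  img <- raw(stride * H)
  for (i in seq_len(H)) {
    y <- H - i + 1L                # bottom-up
    row <- raw(W * 3L)
    row[seq(1L, by = 3L, length.out = W)] <- as.raw(grid$samples[y, , 3L])
    row[seq(2L, by = 3L, length.out = W)] <- as.raw(grid$samples[y, , 2L])
    row[seq(3L, by = 3L, length.out = W)] <- as.raw(grid$samples[y, , 1L])
    img[((i - 1L) * stride + 1L):((i - 1L) * stride + W * 3L)] <- row
  }
  file_size <- 54L + length(img)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("BM"), u32le(file_size), u32le(0L), u32le(54L)), con)
  writeBin(c(u32le(40L), u32le(W), u32le(H), u16le(1L), u16le(24L),
             u32le(0L), u32le(length(img)), u32le(2835L), u32le(2835L),
             u32le(0L), u32le(0L)), con)
  writeBin(img, con)
  invisible(path)
}
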