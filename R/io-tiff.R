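# TIFF, baseline subset: grayscale / RGB, 8 or 16 bits per sample,
# contiguous planar configuration, strip-organized, compression none (1) or
# deflate (8, a zlib stream handled by memDecompress).  The writer emits
# classic little-endian uncompressed single-strip files; the reader accepts
# either byte order.

TAG_WIDTH <- 256L; TAG_HEIGHT <- 257L; TAG_BPS <- 258L; TAG_COMPRESSION <- 259L
TAG_PHOTO <- 262L; TAG_STRIP_OFF <- 273L; TAG_SPP <- 277L; TAG_ROWS_STRIP <- 278L
TAG_STRIP_CNT <- 279L; TAG_PLANAR <- 284L; TAG_PREDICTOR <- 317L

tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

read_tiff <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 8L) format_error("not a TIFF file")
  endian <- if (identical(bytes[1:2], charToRaw("II"))) "little"
            else if (identical(bytes[1:2], charToRaw("MM"))) "big"
            else format_error("not a TIFF file")
  if (rd_uint(bytes[3:4], endian) != 42) format_error("bad TIFF version")
  ifd_off <- rd_uint(bytes[5:8], endian)
  if (ifd_off + 1L > length(bytes)) corrupt_error("TIFF IFD offset out of range")
  nent <- rd_uint(bytes[(ifd_off + 1L):(ifd_off + 2L)], endian)
  tags <- list()
  for (i in seq_len(nent)) {
    e0 <- ifd_off + 2L + (i - 1L) * 12L
    ent <- bytes[(e0 + 1L):(e0 + 12L)]
    tag <- rd_uint(ent[1:2], endian)
    type <- rd_uint(ent[3:4], endian)
    count <- rd_uint(ent[5:8], endian)
    size <- tiff_type_size[as.character(type)]
    if (is.na(size)) next
    nb <- size * count
    vraw <- if (nb <= 4L) ent[9:(8L + nb)] else {
      off <- rd_uint(ent[9:12], endian)
      if (off + nb > length(bytes)) corrupt_error("TIFF tag value offset out of range")
      bytes[(off + 1L):(off + nb)]
    }
    vals <- if (size == 1L) as.numeric(vraw)
            else vapply(seq_len(count), function(k)
              rd_uint(vraw[((k - 1L) * size + 1L):(k * size)], endian), 0)
    tags[[as.character(tag)]] <- vals
  }
  gv <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v
  }
  W <- gv(TAG_WIDTH); H <- gv(TAG_HEIGHT)
  if (is.null(W) || is.null(H)) format_error("TIFF missing dimensions")
  spp <- gv(TAG_SPP, 1L)
  bps <- gv(TAG_BPS, rep(1L, spp))
  comp <- gv(TAG_COMPRESSION, 1L)
  photo <- gv(TAG_PHOTO, 1L)
  planar <- gv(TAG_PLANAR, 1L)
  pred <- gv(TAG_PREDICTOR, 1L)
  if (!spp %in% c(1, 3) || length(unique(bps)) != 1L || !bps[1] %in% c(8, 16))
    format_error(sprintf("unsupported TIFF layout: %g samples/pixel at %s bits",
                         spp, paste(bps, collapse = "/")))
  if (!comp %in% c(1, 8))
    format_error(sprintf("unsupported TIFF compression %g (only none/deflate)", comp))
  if (planar != 1) format_error("unsupported TIFF planar configuration")
  if (pred != 1) format_error("unsupported TIFF predictor")
  if (!photo %in% c(0, 1, 2)) format_error("unsupported TIFF photometric interpretation")
  offs <- gv(TAG_STRIP_OFF); cnts <- gv(TAG_STRIP_CNT)
  if (is.null(offs) || is.null(cnts) || length(offs) != length(cnts))
    format_error("TIFF missing strip layout")
  data <- do.call(c, lapply(seq_along(offs), function(k) {
    if (offs[k] + cnts[k] > length(bytes)) corrupt_error("TIFF strip out of range")
    strip <- bytes[(offs[k] + 1L):(offs[k] + cnts[k])]
    if (comp == 8) memDecompress(strip, type = "gzip") else strip
  }))
  depth <- as.integer(bps[1]); C <- as.integer(spp)
  need <- H * W * C * (depth / 8L)
  if (length(data) < need) corrupt_error("TIFF pixel data shorter than expected")
  arr <- decode_interleaved(data[seq_len(need)], H, W, C, depth, endian)
  if (photo == 0) arr <- (2L^depth - 1L) - arr  # white-is-zero
  pixel_grid(arr, bit_depth = depth)
}

write_tiff <- function(grid, path) {
  C <- grid$channels; depth <- grid$bit_depth
  pix <- encode_interleaved(grid, "little")
  data_off <- 8L
  extra_off <- data_off + length(pix)
  # BitsPerSample for RGB needs 3 shorts = 6 bytes, stored out of line
  extra <- if (C == 3L) c(u16le(depth), u16le(depth), u16le(depth)) else raw(0)
  ifd_off <- extra_off + length(extra)
  entry <- function(tag, type, count, value_raw)
    c(u16le(tag), u16le(type), u32le(count),
      c(value_raw, raw(4L - length(value_raw)))[1:4])
  short_val <- function(x) u16le(x)
  entries <- list(
    entry(TAG_WIDTH, 3L, 1L, short_val(grid$width)),
    entry(TAG_HEIGHT, 3L, 1L, short_val(grid$height)),
    if (C == 3L) entry(TAG_BPS, 3L, 3L, u32le(extra_off))
    else entry(TAG_BPS, 3L, 1L, short_val(depth)),
    entry(TAG_COMPRESSION, 3L, 1L, short_val(1L)),
    entry(TAG_PHOTO, 3L, 1L, short_val(if (C == 3L) 2L else 1L)),
    entry(TAG_STRIP_OFF, 4L, 1L, u32le(data_off)),
    entry(TAG_SPP, 3L, 1L, short_val(C)),
    entry(TAG_ROWS_STRIP, 3L, 1L, short_val(grid$height)),
    entry(TAG_STRIP_CNT, 4L, 1L, u32le(length(pix))),
    entry(TAG_PLANAR, 3L, 1L, short_val(1L)))
  ifd <- c(u16le(length(entries)), do.call(c, entries), u32le(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42L, 0L)), u32le(ifd_off)), con)
  writeBin(pix, con)
  if (length(extra)) writeBin(extra, con)
  writeBin(ifd, con)
  invisible(path)
}
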