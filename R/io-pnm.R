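# PNM (portable anymap): P2/P3 ASCII and P5/P6 binary, maxval up to 65535.
# Parsing accepts comment lines (# ... \n) and arbitrary whitespace between
# header tokens, per the de-facto standard; binary payload starts after the
# single whitespace byte that terminates the maxval token.

read_pnm <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  is_ws <- function(b) b %in% as.raw(c(0x20, 0x09, 0x0A, 0x0D, 0x0B, 0x0C))
  pos <- 1L
  next_token <- function() {
    repeat {
      while (pos <= length(bytes) && is_ws(bytes[pos])) pos <<- pos + 1L
      if (pos <= length(bytes) && bytes[pos] == charToRaw("#")) {
        while (pos <= length(bytes) && bytes[pos] != as.raw(0x0A)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= length(bytes) && !is_ws(bytes[pos]) &&
           bytes[pos] != charToRaw("#")) pos <<- pos + 1L
    if (pos == start) format_error("malformed PNM header: unexpected end of file")
    rawToChar(bytes[start:(pos - 1L)])
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    format_error(sprintf("unsupported PNM magic '%s'", magic))
  W <- suppressWarnings(as.integer(next_token()))
  H <- suppressWarnings(as.integer(next_token()))
  maxval <- suppressWarnings(as.integer(next_token()))
  if (anyNA(c(W, H, maxval)) || W < 1L || H < 1L || maxval < 1L || maxval > 65535L)
    format_error("malformed PNM header: bad dimensions or maxval")
  depth <- if (maxval > 255L) 16L else 8L
  C <- if (magic %in% c("P3", "P6")) 3L else 1L
  if (magic %in% c("P5", "P6")) {
    pos <- pos + 1L  # exactly one whitespace byte after maxval
    need <- H * W * C * (depth / 8L)
    if (length(bytes) - pos + 1L < need)
      format_error("truncated PNM pixel data")
    arr <- decode_interleaved(bytes[pos:(pos + need - 1L)], H, W, C, depth, "big")
  } else {
    txt <- rawToChar(bytes[pos:length(bytes)])
    txt <- gsub("#[^\n]*", " ", txt)
    v <- suppressWarnings(as.integer(strsplit(trimws(txt), "\\s+")[[1]]))
    if (anyNA(v) || length(v) < H * W * C)
      format_error("malformed ASCII PNM pixel data")
    v <- v[seq_len(H * W * C)]
    arr <- aperm(array(v, dim = c(C, W, H)), c(3L, 2L, 1L))
  }
  if (max(arr) > maxval) format_error("PNM sample exceeds declared maxval")
  pixel_grid(arr, bit_depth = depth)
}

write_pnm <- function(grid, path) {
  magic <- if (grid$channels == 1L) "P5" else "P6"
  maxval <- 2L^grid$bit_depth - 1L
  header <- sprintf("%s\n%d %d\n%d\n", magic, grid$width, grid$height, maxval)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(encode_interleaved(grid, "big"), con)
  invisible(path)
}
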