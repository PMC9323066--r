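# The .tdc container: header + canonical codebook + bit-packed payload.
#
# Layout (all little-endian):
#   magic "TDC1" | u8 version | u32 H | u32 W | u8 channels | u8 bit_depth |
#   u8 levels | u32 codebook entry count | entries as (i32 symbol, u8 length) |
#   u64 payload bit count | payload bits MSB-first, zero-padded to a byte.
#
# One codebook is shared across channels and levels: base samples and signed
# details are carried in a single signed-integer alphabet covering only the
# symbols actually observed.  The header alone sizes every buffer before the
# payload is touched, so truncation is always detected before decoding.

TDC_MAGIC <- charToRaw("TDC1")
TDC_VERSION <- 1L

format_error <- function(msg)
  stop(errorCondition(msg, class = c("difftx_format_error", "error", "condition")))
corrupt_error <- function(msg)
  stop(errorCondition(msg, class = c("difftx_corrupt_error", "error", "condition")))

#' Encode a coefficient pyramid into .tdc container bytes
#'
#' Serializes the coefficient stream (column-major per channel, channels in
#' order) with a single static canonical Huffman code built from the
#' observed symbol frequencies.  Output is byte-identical for identical
#' input: the codebook construction is deterministic and the payload order
#' is fixed.
#'
#' @param coeffs `coeff_grid` from [decompose()].
#' @param spec matching `pyramid_spec`.
#' @return raw vector: the complete container.
#' @export
tdc_encode <- function(coeffs, spec) {
  stopifnot(inherits(coeffs, "coeff_grid"), inherits(spec, "pyramid_spec"))
  stream <- as.vector(coeffs$values)
  tab <- sort(unique(stream))
  cnt <- tabulate(match(stream, tab), nbins = length(tab))
  cb <- build_codebook(tab, cnt)
  idx <- match(stream, cb$symbols) - 1L
  packed <- .huff_pack(idx, cb$lengths)

  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(TDC_MAGIC, con)
  writeBin(as.raw(TDC_VERSION), con)
  writeBin(as.integer(c(spec$height, spec$width)), con, size = 4L, endian = "little")
  writeBin(as.raw(c(spec$channels, spec$bit_depth, spec$levels)), con)
  writeBin(length(cb$symbols), con, size = 4L, endian = "little")
  entries <- raw(5L * length(cb$symbols))
  sym_bytes <- writeBin(cb$symbols, raw(), size = 4L, endian = "little")
  entries[rep(seq(1L, length(entries), by = 5L), each = 4L) + 0:3] <- sym_bytes
  entries[seq(5L, length(entries), by = 5L)] <- as.raw(cb$lengths)
  writeBin(entries, con)
  nbits <- packed$nbits
  writeBin(as.raw(nbits %/% 256^(0:7) %% 256), con)  # u64, little-endian
  writeBin(packed$bytes, con)
  rawConnectionValue(con)
}

#' Decode .tdc container bytes
#'
#' Exact inverse of [tdc_encode()].  A wrong magic or unsupported version
#' raises a `difftx_format_error`; a stream shorter than its header promises
#' raises a `difftx_corrupt_error` naming the byte offset, as does a payload
#' that exhausts or over-runs its declared bit count.
#'
#' @param bytes raw vector as produced by [tdc_encode()].
#' @return list with `coeffs` (`coeff_grid`) and `spec` (`pyramid_spec`).
#' @export
tdc_decode <- function(bytes) {
  if (!is.raw(bytes)) format_error("input is not raw bytes")
  need <- function(n, at, what)
    if (length(bytes) < at + n - 1L)
      corrupt_error(sprintf("truncated container: need %d bytes for %s at byte offset %d, have %d",
                            n, what, at - 1L, length(bytes)))
  need(4L, 1L, "magic")
  if (!identical(bytes[1:4], TDC_MAGIC))
    format_error("bad magic: not a TDC stream")
  need(1L, 5L, "version")
  if (as.integer(bytes[5]) != TDC_VERSION)
    format_error(sprintf("unsupported container version %d", as.integer(bytes[5])))
  need(11L, 6L, "geometry header")
  H <- readBin(bytes[6:9], "integer", size = 4L, endian = "little")
  W <- readBin(bytes[10:13], "integer", size = 4L, endian = "little")
  channels <- as.integer(bytes[14])
  bit_depth <- as.integer(bytes[15])
  levels <- as.integer(bytes[16])
  need(4L, 17L, "codebook size")
  ncode <- readBin(bytes[17:20], "integer", size = 4L, endian = "little")
  if (ncode < 1L) corrupt_error("empty codebook")
  need(5L * ncode, 21L, "codebook entries")
  ent <- bytes[21:(20L + 5L * ncode)]
  sym_idx <- rep(seq(1L, 5L * ncode, by = 5L), each = 4L) + 0:3
  symbols <- readBin(ent[sym_idx], "integer", n = ncode, size = 4L, endian = "little")
  lengths <- as.integer(ent[seq(5L, 5L * ncode, by = 5L)])
  pos <- 21L + 5L * ncode
  need(8L, pos, "payload bit count")
  nbits <- sum(as.numeric(bytes[pos:(pos + 7L)]) * 256^(0:7))
  pos <- pos + 8L
  nbytes <- ceiling(nbits / 8)
  need(nbytes, pos, "payload")
  payload <- bytes[seq_len(nbytes) + pos - 1L]

  count <- as.numeric(H) * W * channels
  if (any(lengths < 1L) || any(diff(lengths) < 0L))
    corrupt_error("codebook lengths not canonical")
  idx <- .huff_unpack(payload, nbits, lengths, count)
  vals <- symbols[idx + 1L]
  dim(vals) <- c(H, W, channels)
  list(coeffs = coeff_grid(vals, bit_depth = bit_depth),
       spec = pyramid_spec(H, W, channels, bit_depth, levels))
}

#' Compress a pixel grid to container bytes
#'
#' Convenience composition: [decompose()] then [tdc_encode()].
#'
#' @param grid `pixel_grid`.
#' @param levels level count or `"max"`.
#' @return raw vector.
#' @export
tdc_compress_grid <- function(grid, levels = "max") {
  d <- decompose(grid, levels)
  tdc_encode(d$coeffs, d$spec)
}

#' Decompress container bytes back to the original pixel grid
#'
#' @param bytes raw vector from [tdc_compress_grid()].
#' @return `pixel_grid`, sample-identical to the encoded original.
#' @export
tdc_decompress_grid <- function(bytes) {
  d <- tdc_decode(bytes)
  reconstruct(d$coeffs, d$spec)
}
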