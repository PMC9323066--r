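# Container encode/decode: losslessness, determinism, entropy bounds,
# and corruption handling.

encode_grid <- function(g, levels = "max") {
  d <- decompose(g, levels)
  tdc_encode(d$coeffs, d$spec)
}

test_that("decode(encode(x)) is the identity over random grids", {
  set.seed(111)
  for (i in 1:200) {
    H <- sample(3:20, 1L); W <- sample(3:20, 1L)
    d <- sample(c(8L, 16L), 1L); C <- sample(c(1L, 3L), 1L)
    g <- rand_grid(H, W, C, d)
    expect_roundtrip(g)
  }
})

test_that("header fields survive the round trip exactly", {
  g <- rand_grid(11L, 7L, 3L, 16L)
  d <- decompose(g, 2L)
  out <- tdc_decode(tdc_encode(d$coeffs, d$spec))
  expect_identical(out$spec$height, 11L)
  expect_identical(out$spec$width, 7L)
  expect_identical(out$spec$channels, 3L)
  expect_identical(out$spec$bit_depth, 16L)
  expect_identical(out$spec$levels, 2L)
  expect_identical(out$coeffs$values, d$coeffs$values)
})

test_that("encoding is byte-deterministic", {
  set.seed(222)
  g <- rand_grid(16L, 16L)
  expect_identical(encode_grid(g), encode_grid(g))
})

test_that("mean code length is sandwiched by the stream entropy", {
  set.seed(333)
  for (i in 1:10) {
    g <- rand_grid(16L, 16L, sample(c(1L, 3L), 1L))
    d <- decompose(g, "max")
    stream <- as.vector(d$coeffs$values)
    tab <- table(stream)
    cb <- build_codebook(as.integer(names(tab)), as.numeric(tab))
    st <- codebook_stats(cb, as.numeric(tab)[match(cb$symbols, as.integer(names(tab)))])
    expect_gte(st$mean_length, st$entropy)
    expect_lt(st$mean_length, st$entropy + 1)
  }
})

test_that("bad magic and unsupported versions are format errors", {
  g <- fixture_grid("constant", 4L, 4L)
  b <- encode_grid(g)
  bad <- b; bad[1] <- as.raw(0x58)
  expect_error(tdc_decode(bad), class = "difftx_format_error")
  bad <- b; bad[5] <- as.raw(99L)
  expect_error(tdc_decode(bad), class = "difftx_format_error")
  expect_error(tdc_decode(charToRaw("x")), class = "difftx_corrupt_error")
})

test_that("truncation is reported with a byte offset", {
  set.seed(444)
  b <- encode_grid(rand_grid(8L, 8L))
  err <- tryCatch(tdc_decode(b[1:(length(b) - 3L)]), error = identity)
  expect_s3_class(err, "difftx_corrupt_error")
  expect_match(conditionMessage(err), "byte offset")
})

test_that("payload bit flips never pass silently", {
  set.seed(555)
  for (i in 1:25) {
    g <- rand_grid(sample(4:12, 1L), sample(4:12, 1L))
    b <- encode_grid(g)
    ncode <- readBin(b[17:20], "integer", size = 4L, endian = "little")
    pstart <- 20L + 5L * ncode + 8L
    pos <- sample((pstart + 1L):length(b), 1L)
    bit <- sample(0:7, 1L)
    b[pos] <- xor(b[pos], as.raw(bitwShiftL(1L, bit)))
    got <- tryCatch(tdc_decompress_grid(b), error = identity)
    if (inherits(got, "error")) succeed()
    else expect_false(grids_identical(g, got))
  }
})

test_that("an all-constant image compresses to near-nothing beyond the header", {
  g <- fixture_grid("constant", 64L, 64L)
  b <- encode_grid(g)
  # 4096 symbols from a 3-symbol-ish alphabet: payload must be < 2 bits/sample
  expect_lt(length(b), 64 * 64 * 2 / 8 + 200)
  expect_true(grids_identical(g, tdc_decompress_grid(b)))
})
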