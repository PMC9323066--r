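# Raster readers/writers: format round trips, header conventions,
# cross-reader agreement, capability errors.

test_that("every format round-trips its supported depth/channel combos", {
  set.seed(1001)
  cases <- expand.grid(C = c(1L, 3L), d = c(8L, 16L))
  for (k in seq_len(nrow(cases))) {
    g <- rand_grid(13L, 9L, cases$C[k], cases$d[k])
    for (fmt in c("pnm", "png", "tiff")) {
      p <- withr::local_tempfile(fileext = ".img")
      write_image(g, p, fmt)
      rec <- read_image(p)
      expect_identical(rec$format, fmt)
      expect_true(grids_identical(rec$grid, g))
      expect_identical(rec$bytes, file.size(p))
    }
  }
  g <- rand_grid(13L, 9L, 3L, 8L)
  p <- withr::local_tempfile(fileext = ".bmp")
  write_image(g, p, "bmp")
  expect_true(grids_identical(read_image(p)$grid, g))
})

test_that("PNM writer emits the canonical header and exact payload size", {
  g <- pixel_grid(array(0:15, c(4L, 4L, 1L)), 8L)
  p <- withr::local_tempfile(fileext = ".pgm")
  expect_identical(as.integer(write_image(g, p)), 27L)  # "P5\n4 4\n255\n" + 16
  expect_identical(rawToChar(readBin(p, "raw", 11L)), "P5\n4 4\n255\n")
  # PNM round trips are byte-identical for canonical headers
  g2 <- read_image(p)$grid
  p2 <- withr::local_tempfile(fileext = ".pgm")
  write_image(g2, p2)
  expect_identical(readBin(p, "raw", 27L), readBin(p2, "raw", 27L))
})

test_that("PNM parsing handles comments, whitespace and ASCII variants", {
  p <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "# a comment", "3  3", "# another", "255",
               "0 10 20", "30 40 50", "60 70 80"), p)
  g <- read_image(p)$grid
  expect_identical(g$samples[, , 1L], matrix(seq(0L, 80L, 10L), 3L, byrow = TRUE))
  p3 <- withr::local_tempfile(fileext = ".ppm")
  writeLines(c("P3", "3 3", "15", paste(rep(0:8, each = 3), collapse = " ")), p3)
  g3 <- read_image(p3)$grid
  expect_identical(g3$channels, 3L)
  expect_identical(g3$samples[3L, 2L, ], rep(7L, 3L))
  # binary 16-bit PGM is big-endian
  p16 <- withr::local_tempfile(fileext = ".pgm")
  con <- file(p16, "wb")
  writeBin(charToRaw("P5\n3 3\n65535\n"), con)
  writeBin(as.raw(c(rbind(0:8, 9:17))), con)  # pairs (hi, lo)
  close(con)
  g16 <- read_image(p16)$grid
  expect_identical(g16$bit_depth, 16L)
  expect_identical(g16$samples[1L, 1L, 1L], 0L * 256L + 9L)
  expect_identical(g16$samples[3L, 3L, 1L], 8L * 256L + 17L)
})

test_that("malformed or unsupported files raise typed errors", {
  p <- withr::local_tempfile(fileext = ".pgm")
  writeLines("P7 not a real header", p)
  expect_error(read_image(p), class = "difftx_format_error")
  writeBin(as.raw(1:20), p)
  expect_error(read_image(p), class = "difftx_format_error")
  p2 <- withr::local_tempfile(fileext = ".pgm")
  writeChar("P5\n100 100\n255\n", p2, eos = NULL)  # promises more pixels than present
  expect_error(read_image(p2), class = "difftx_format_error")
  expect_error(read_image(withr::local_tempfile()), "no such file")
})

test_that("PNG reader rejects what it cannot decode and verifies CRCs", {
  g <- rand_grid(5L, 5L)
  p <- withr::local_tempfile(fileext = ".png")
  write_image(g, p, "png")
  b <- readBin(p, "raw", file.size(p))
  b[30] <- xor(b[30], as.raw(1L))  # inside IHDR -> CRC mismatch
  writeBin(b, p)
  expect_error(read_image(p), class = "difftx_corrupt_error")
})

test_that("readers agree with an independently written reference (Pillow)", {
  py <- Sys.which("python")
  if (!nzchar(py)) skip("python not on PATH")
  dir <- withr::local_tempdir()
  script <- file.path(dir, "mk.py")
  writeLines(c(
    "import numpy as np",
    "from PIL import Image",
    "rng = np.random.default_rng(9)",
    "a = rng.integers(0, 256, (7, 10, 3), dtype=np.uint8)",
    sprintf("Image.fromarray(a).save(r'%s/ref.png')", dir),
    sprintf("Image.fromarray(a).save(r'%s/ref.tif', compression='tiff_deflate')", dir),
    sprintf("Image.fromarray(a).save(r'%s/ref.bmp')", dir),
    sprintf("Image.fromarray(a).save(r'%s/ref.ppm')", dir)), script)
  if (system2(py, script, stdout = FALSE, stderr = FALSE) != 0L)
    skip("python image oracle unavailable")
  ref <- read_image(file.path(dir, "ref.ppm"))$grid
  for (ext in c("png", "tif", "bmp"))
    expect_true(grids_identical(read_image(file.path(dir, paste0("ref.", ext)))$grid, ref))
})

test_that("compression_ratio follows its definition and allows sub-unity values", {
  expect_equal(compression_ratio(1000, 1000), 1)
  expect_equal(compression_ratio(1000, 250), 4)
  expect_lt(compression_ratio(500, 3000), 1)
  expect_error(compression_ratio(0, 10), "positive")
})
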