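# Single-level transform: worked examples, properties, and exact inverses.

test_that("forward_1d matches hand-derived examples", {
  expect_equal(forward_1d(c(7L, 7L, 7L, 7L)),
               list(evens = c(7L, 7L), details = c(0L, 0L)))
  # right edge of an even-length sequence replicates the last even sample
  expect_equal(forward_1d(c(10L, 12L, 14L, 16L)),
               list(evens = c(10L, 14L), details = c(0L, -2L)))
  # the near-extreme of the 8-bit coefficient interval
  expect_equal(forward_1d(c(0L, 255L, 0L)),
               list(evens = c(0L, 0L), details = c(-255L)))
  expect_equal(forward_1d(c(255L, 0L, 255L))$details, 255L)
})

test_that("forward_1d rejects bad input", {
  expect_error(forward_1d(c(1L, 2L)), "length")
  expect_error(forward_1d(c(1.5, 2, 3)), "integer")
  expect_error(forward_1d(c(-1L, 2L, 3L)), "integer")
})

test_that("inverse_1d inverts forward_1d over random sequences", {
  expect_equal(inverse_1d(c(7L, 7L), c(0L, 0L), 4L), rep(7L, 4L))
  expect_equal(inverse_1d(c(10L, 14L), c(0L, -2L), 4L), c(10L, 12L, 14L, 16L))
  set.seed(101)
  for (i in 1:1000) {
    L <- sample(3:64, 1L)
    depth <- sample(c(8L, 16L), 1L)
    x <- sample.int(2L^depth, L, replace = TRUE) - 1L
    f <- forward_1d(x)
    expect_length(c(f$evens, f$details), L)
    expect_identical(inverse_1d(f$evens, f$details, L), x)
  }
})

test_that("inverse_1d validates lengths", {
  expect_error(inverse_1d(c(1L, 2L), c(0L), 5L), "length")
  expect_error(inverse_1d(c(1L), c(0L, 0L), 4L), "length")
})

test_that("forward_2d agrees with the naive double-loop oracle", {
  set.seed(202)
  for (i in 1:50) {
    H <- sample(3:9, 1L); W <- sample(3:9, 1L)
    m <- rand_plane(H, W)
    expect_identical(forward_2d(m)$values[, , 1L], naive_fwd2d(m))
  }
  # and on the spec'd 8x8 / 9x7 shapes at 16 bits
  for (hw in list(c(8L, 8L), c(9L, 7L))) {
    m <- rand_plane(hw[1], hw[2], 16L)
    expect_identical(forward_2d(m, 16L)$values[, , 1L], naive_fwd2d(m))
  }
})

test_that("forward_2d: constants give an exact WS copy and zero details", {
  co <- forward_2d(matrix(9L, 4L, 4L))
  expect_identical(co$values[1:2, 1:2, 1L], matrix(9L, 2L, 2L))
  expect_true(all(detail_values(co$values[, , 1L], 4L, 4L) == 0L))
})

test_that("forward_2d on the 5x5 additive ramp keeps details in {0, -1}", {
  m <- outer(0:4, 0:4, `+`)
  co <- forward_2d(m)
  expect_identical(co$values[1:3, 1:3, 1L], matrix(m[c(1, 3, 5), c(1, 3, 5)], 3L))
  expect_true(all(detail_values(co$values[, , 1L], 5L, 5L) %in% c(0L, -1L)))
  expect_true(grids_identical(inverse_2d(co), pixel_grid(m, 8L)))
})

test_that("2D round trip is bit-exact for both parities and both depths", {
  set.seed(303)
  for (H in c(3L, 4L, 7L, 8L)) for (W in c(3L, 4L, 9L)) for (d in c(8L, 16L)) {
    g <- rand_grid(H, W, 1L, d)
    expect_true(grids_identical(inverse_2d(forward_2d(g)), g))
  }
})

test_that("detail coefficients stay inside [-2^N, 2^N] and attain +/-(2^N - 1)", {
  seen <- integer(0)
  set.seed(404)
  for (i in 1:40) {
    m <- rand_plane(sample(3:16, 1L), sample(3:16, 1L))
    seen <- range(c(seen, detail_values(forward_2d(m)$values[, , 1L], nrow(m), ncol(m))))
  }
  expect_gte(min(seen), -2L^8)
  expect_lte(max(seen), 2L^8)
  # extremes attained by alternating min/max on the even grid
  m <- matrix(0L, 3L, 3L); m[1L, 2L] <- 255L
  expect_equal(min(forward_2d(m)$values), -255L)
  m2 <- matrix(255L, 3L, 3L); m2[1L, 2L] <- 0L
  expect_equal(max(forward_2d(m2)$values), 255L)
})

test_that("inverse filtering passes commute", {
  set.seed(505)
  g <- rand_grid(8L, 8L)
  co <- forward_2d(pixel_grid(g$samples[, , 1L], 8L))
  orders <- list(c("H","V","D"), c("H","D","V"), c("V","H","D"),
                 c("V","D","H"), c("D","H","V"), c("D","V","H"))
  outs <- lapply(orders, function(o) inverse_2d(co, order = o)$samples)
  for (k in 2:6) expect_identical(outs[[k]], outs[[1]])
})

test_that("coefficient count equals sample count", {
  set.seed(606)
  for (hw in list(c(3L, 5L), c(6L, 4L), c(7L, 7L))) {
    g <- rand_grid(hw[1], hw[2])
    expect_length(forward_2d(g)$values, length(g$samples))
  }
})

test_that("pixel_grid and forward_2d validate their domains", {
  expect_error(pixel_grid(matrix(0L, 2L, 5L)), ">= 3")
  expect_error(pixel_grid(matrix(300L, 4L, 4L), 8L), "range")
  expect_error(pixel_grid(array(0L, c(4L, 4L, 2L))), "channels")
  expect_error(forward_2d(matrix(0L, 2L, 8L)), "3 x 3")
})

test_that("the shared filter has zero-sum symmetric taps", {
  h <- diff_filter()
  expect_equal(sum(h), 0)
  expect_equal(h[["-1"]], h[["1"]])
})
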