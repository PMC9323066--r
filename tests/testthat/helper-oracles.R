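# Independent oracles and random-input helpers shared across the suite.
# These re-derive expected values by brute force and must stay independent
# of the implementation paths they check.

# random integer plane / grid at a given depth
rand_plane <- function(H, W, depth = 8L) {
  matrix(sample.int(2L^depth, H * W, replace = TRUE) - 1L, H, W)
}

rand_grid <- function(H, W, C = 1L, depth = 8L) {
  a <- array(sample.int(2L^depth, H * W * C, replace = TRUE) - 1L, c(H, W, C))
  pixel_grid(a, bit_depth = depth)
}

# naive cell-by-cell single-level 2D transform: a literal double loop over
# the four quadrant definitions with clamped even-grid neighbor indexing
naive_fwd2d <- function(m) {
  H <- nrow(m); W <- ncol(m)
  f <- function(y, x) {             # 0-based, clamped to the even grid
    ylast <- if (H %% 2L == 0L) H - 2L else H - 1L
    xlast <- if (W %% 2L == 0L) W - 2L else W - 1L
    m[min(y, ylast) + 1L, min(x, xlast) + 1L]
  }
  ch <- ceiling(H / 2); cw <- ceiling(W / 2)
  fh <- floor(H / 2); fw <- floor(W / 2)
  out <- matrix(0L, H, W)
  for (n in 0:(ch - 1L)) for (m_ in 0:(cw - 1L))
    out[n + 1L, m_ + 1L] <- m[2L * n + 1L, 2L * m_ + 1L]             # WS
  for (n in 0:(ch - 1L)) for (m_ in 0:(fw - 1L))                      # WH
    out[n + 1L, cw + m_ + 1L] <-
      floor((f(2 * n, 2 * m_) + f(2 * n, 2 * m_ + 2)) / 2) - m[2L * n + 1L, 2L * m_ + 2L]
  for (n in 0:(fh - 1L)) for (m_ in 0:(cw - 1L))                      # WV
    out[ch + n + 1L, m_ + 1L] <-
      floor((f(2 * n, 2 * m_) + f(2 * n + 2, 2 * m_)) / 2) - m[2L * n + 2L, 2L * m_ + 1L]
  for (n in 0:(fh - 1L)) for (m_ in 0:(fw - 1L))                      # WD
    out[ch + n + 1L, cw + m_ + 1L] <-
      floor((f(2 * n, 2 * m_) + f(2 * n + 2, 2 * m_ + 2)) / 2) - m[2L * n + 2L, 2L * m_ + 2L]
  storage.mode(out) <- "integer"
  out
}

# exact minimum weighted code length over all prefix trees, by exhaustive
# search over merge sequences (feasible for <= 6 symbols)
brute_optimal_cost <- function(weights) {
  if (length(weights) == 1L) return(0)
  best <- Inf
  n <- length(weights)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    merged <- c(weights[-c(i, j)], weights[i] + weights[j])
    cost <- weights[i] + weights[j] + brute_optimal_cost(merged)
    if (cost < best) best <- cost
  }
  best
}

# detail-coefficient values of a packed single-level plane (everything
# outside the WS quadrant)
detail_values <- function(cm, H, W) {
  ch <- ceiling(H / 2); cw <- ceiling(W / 2)
  mask <- matrix(TRUE, H, W)
  mask[1:ch, 1:cw] <- FALSE
  cm[mask]
}

expect_roundtrip <- function(grid, levels = "max") {
  b <- tdc_compress_grid(grid, levels)
  expect_true(grids_identical(grid, tdc_decompress_grid(b)))
  invisible(b)
}
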