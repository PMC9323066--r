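# Static canonical Huffman coding over the signed coefficient alphabet.
# Tree construction (two-queue method) lives here in R; the bit-level
# encode/decode hot loops are compiled (src/huffman.cpp).

#' Build a canonical Huffman codebook from symbol frequencies
#'
#' Classical optimal prefix-code construction by repeatedly merging the two
#' lowest-weight subtrees, implemented with the two-queue method: leaves are
#' pre-sorted by `(count, symbol)` and merged nodes join a second queue in
#' nondecreasing weight order, so every merge is O(1).  Ties between the
#' queue fronts are broken in favor of the leaf queue; together with the
#' leaf pre-sort this makes construction fully deterministic -- identical
#' frequency tables always yield identical codebooks.  Only code *lengths*
#' are kept; actual bits are assigned canonically (symbols sorted by length
#' then value, codes counted upward), which is what makes the serialized
#' form compact: `(symbol, length)` pairs reconstruct the codes exactly.
#'
#' A single-symbol alphabet is assigned a 1-bit code so that every payload
#' symbol occupies at least one bit and decoding never divides by zero.
#'
#' @param symbols integer vector of distinct symbol values.
#' @param counts positive counts, parallel to `symbols`.
#' @return object of class `huffman_codebook`: a list with `symbols` and
#'   `lengths` sorted in canonical order, plus the total `count`.
#' @examples
#' cb <- build_codebook(c(-1L, 0L, 1L, 2L), c(2L, 5L, 1L, 1L))
#' cb$lengths
#' @export
build_codebook <- function(symbols, counts) {
  if (length(symbols) == 0L) stop("empty frequency table")
  if (length(symbols) != length(counts)) stop("symbols/counts length mismatch")
  symbols <- as.integer(symbols)
  counts <- as.numeric(counts)
  if (anyDuplicated(symbols)) stop("duplicate symbols")
  if (any(counts <= 0)) stop("all counts must be positive")
  n <- length(symbols)
  if (n == 1L) {
    cb <- list(symbols = symbols, lengths = 1L, count = counts)
    class(cb) <- "huffman_codebook"
    return(cb)
  }
  o <- order(counts, symbols)
  lw <- counts[o]                       # leaf queue weights (sorted)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  mw <- numeric(n - 1L)                 # merged-node queue weights
  i <- 1L                               # leaf queue front
  jf <- 1L; jb <- 0L                    # merged queue front / back
  take <- function() {
    # smallest of the two queue fronts; ties prefer the leaf
    if (i <= n && (jf > jb || lw[i] <= mw[jf])) {
      id <- i; w <- lw[i]; i <<- i + 1L; c(id, w)
    } else {
      id <- n + jf; w <- mw[jf]; jf <<- jf + 1L; c(id, w)
    }
  }
  for (k in seq_len(n - 1L)) {
    a <- take(); b <- take()
    jb <- jb + 1L
    mw[jb] <- a[2] + b[2]
    parent[a[1]] <- n + jb
    parent[b[1]] <- n + jb
  }
  depth <- integer(n_nodes)
  for (id in (n_nodes - 1L):1L) depth[id] <- depth[parent[id]] + 1L
  lens <- integer(n)
  lens[o] <- depth[seq_len(n)]
  can <- order(lens, symbols)
  cb <- list(symbols = symbols[can], lengths = lens[can],
             count = sum(counts))
  class(cb) <- "huffman_codebook"
  cb
}

#' Canonical code bits of a codebook
#'
#' Reconstructs the canonical code of every entry as a bit string; mainly
#' for inspection and for the optimality tests.  Codes are assigned in
#' canonical order: `code_1 = 0`, `code_{k+1} = (code_k + 1) << (len_{k+1}
#' - len_k)`.
#'
#' @param cb a `huffman_codebook`.
#' @return character vector of "0"/"1" strings, parallel to `cb$symbols`.
#' @export
codebook_codes <- function(cb) {
  stopifnot(inherits(cb, "huffman_codebook"))
  lens <- cb$lengths
  if (any(lens > 53L)) stop("code too long to render exactly")
  code <- 0
  out <- character(length(lens))
  prev <- lens[1]
  for (k in seq_along(lens)) {
    if (k > 1L) {
      code <- (code + 1) * 2^(lens[k] - prev)
      prev <- lens[k]
    }
    bits <- if (lens[k] > 0)
      paste(rev((code %/% 2^(seq_len(lens[k]) - 1)) %% 2), collapse = "")
    else ""
    out[k] <- bits
  }
  out
}

#' Mean code length and empirical entropy of a codebook
#'
#' @param cb a `huffman_codebook`.
#' @param counts observed counts in the same order as `cb$symbols`; by
#'   default the counts the book was built from are not retained per-symbol,
#'   so they must be supplied for entropy.
#' @return list with `mean_length` (bits/symbol) and `entropy` (bits/symbol).
#' @export
codebook_stats <- function(cb, counts) {
  stopifnot(inherits(cb, "huffman_codebook"),
            length(counts) == length(cb$symbols))
  p <- counts / sum(counts)
  list(mean_length = sum(p * cb$lengths),
       entropy = -sum(p * log2(p)))
}

#' @export
print.huffman_codebook <- function(x, ...) {
  cat(sprintf("<huffman_codebook: %d symbols, lengths %d..%d>\n",
              length(x$symbols), min(x$lengths), max(x$lengths)))
  invisible(x)
}

# Kraft sum; == 1 for every complete Huffman code with >= 2 symbols
kraft_sum <- function(cb) sum(2^(-cb$lengths))
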