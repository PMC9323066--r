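---
title: "The difference transform codec: model, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The difference transform codec: model, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(difftx)
```

## The model

`difftx` implements a reversible integer transform for lossless image
compression. The idea is prediction by neighbor averaging: keep every
even-index sample, and replace each odd sample by how far it falls from the
average of its two even neighbors,

$$d_j = \left\lfloor \tfrac{x_{2j} + x_{2j+2}}{2} \right\rfloor - x_{2j+1},$$

equivalently a subsampled convolution with the three-tap filter
$h = (\tfrac12, -1, \tfrac12)$. Where the image is locally constant or
linear the residual is zero or near zero, so the transform concentrates the
histogram of a smooth image into a narrow spike around zero — exactly the
shape a prefix code exploits. Because the inverse recomputes the *same*
average from the *same* retained samples, the round trip is exact in
integer arithmetic; no growth, no loss, one coefficient per input sample.

In two dimensions the single filter is applied along three directions,
giving the subsampled base `WS` and detail planes `WH` (horizontal, along
the x/column axis), `WV` (vertical) and `WD` (diagonal, predicting
$f(2m{+}1, 2n{+}1)$ from $f(2m,2n)$ and $f(2m{+}2,2n{+}2)$). The base
quadrant is transformed again recursively — a multiresolution pyramid in
the arrangement familiar from wavelet codecs, but with one filter instead
of an analysis/synthesis bank. Each of the three inverse passes reads only
base samples, so the passes commute; the test suite asserts agreement of
all six orders.

The coefficients are entropy-coded with a static two-pass Huffman code and
written to a `.tdc` container whose header alone sizes every decode buffer.

## Conventions the source left open

Several details are under-determined by the transform's defining equations;
the package fixes them as follows, and the choices are load-bearing for
bit-exactness:

* **Rounding.** The neighbor average of two integers can be a
  half-integer. We floor it, identically in forward and inverse. Any single
  fixed rule would round-trip; floor is the cheapest (`%/% 2` on the sum)
  and keeps the attained detail range symmetric at $\pm(2^N - 1)$.
* **Residual centering.** Residuals are centered at *odd* positions. The
  alternative reading (filtering centered on even samples) is not
  invertible, since even samples are the ones retained; the inverse
  equations force this choice.
* **Boundaries.** At the far edge of an even-sized dimension the odd
  sample's right/lower even neighbor does not exist; we replicate the
  nearest in-range even-grid sample (clamped indexing), again identically
  on both sides of the transform.
* **Odd dimensions.** The base keeps the even-index grid, so `WS` takes
  the ceil-half of each dimension and detail quadrants the floor-half. Each
  pyramid level records its own input size (`pyramid_spec$level_dims`), so
  ceil/floor splits nest unambiguously for shapes like 161×64.
* **Pyramid depth.** `max_levels()` applies levels while the base is at
  least 3×3 *and larger than* 3×3: a 3×3 base is the terminus
  (`max_levels(3,3) = 0`, `max_levels(4,4) = 1`, `max_levels(384,288) =
  7`). `decompose()` itself accepts any level count whose every applied
  level sees a base of at least 3×3 — so an explicit single level on a 3×3
  image is legal, matching the single-level transform's own precondition —
  and the CLI default `--levels max` uses `max(1, max_levels())`.
* **Color.** Channels are transformed independently; nothing in the
  transform couples them. All channels then share one entropy coder (below).

## Coefficient alphabet

For an $N$-bit image every detail coefficient lies in $[-2^N, 2^N]$. Under
floor rounding the attainable extremes are exactly $\pm(2^N - 1)$ —
$2^{N+1} - 1$ values, not the $2^{N+1} + 1$ sometimes quoted for this
interval: $+2^N$ would need a rounded-up average, $-2^N$ a rounded-down
one, and no single consistent rounding rule can attain both. The tests
assert containment in the closed interval and witness the attained extremes
with the `[0, max, 0]` construction (residual $-(2^N-1)$) and its
complement.

## Entropy coding and the container

The codebook is a static canonical Huffman code over the union of base
samples and detail values in one signed alphabet, shared across channels
and levels. Rationale: the base quadrant at the deepest level is a tiny
fraction of the coefficients, so mixing it into the detail alphabet costs
little, while one codebook keeps the header small for the small-image
regime where header overhead dominates. For 16-bit inputs the codebook
covers only observed symbols (at most one per pixel), never the full
$2^{17}+1$-value alphabet.

Construction is the two-queue merge with ties broken in favor of the leaf
queue over pre-sorted `(count, symbol)` leaves, making output fully
deterministic; a single-symbol alphabet gets a 1-bit code. Only code
lengths are stored — codes are reassigned canonically on decode — so the
serialized codebook is just `(i32 symbol, u8 length)` pairs. Code lengths
are capped at 64 bits; exceeding the cap would require Fibonacci-growth
frequency tables beyond any addressable image, and the encoder refuses
rather than silently mis-coding. Payload bits are packed MSB-first; the
bit-level encode/decode loops are compiled (Rcpp), everything else is
vectorized R.

Corruption handling is conservative: a wrong magic or version is a
`difftx_format_error`; any byte shortage against the header's promises, a
payload that exhausts before the declared symbol count, or trailing unread
bits raise a `difftx_corrupt_error` with a byte offset. A flipped payload
bit either fails to decode or decodes to a different image — never to a
silent partial acceptance — which the fuzz tests assert.

## What the synthetic generator does and does not establish

The fixture families (`constant`, three ramps, `checkerboard`,
`uniform_noise`, `blob_phantom`) are chosen to bracket the codec's
behavior, not to imitate any particular dataset: constants and ramps are
the transform's best case (zero / near-zero residuals), uniform noise its
worst (full-entropy residuals plus codebook overhead, hence ratios below
1), and the blob phantom — a sum of 3–6 smooth radial bumps on a dark
background, layout drawn from the seed — stands in for the smooth-with-
gradients structure of radiographs. Default battery sizes (3–65 pixels per
side, both parities, 8 and 16 bits, 1 and 3 channels) exercise every
boundary and nesting case at speed; 64×64 is used where a stable ratio
matters.

A green battery therefore establishes *bit-exact losslessness and the
qualitative compression ordering*. It does not establish the absolute
ratios achievable on real medical or photographic data: those depend on
source-container compression (the ratio baseline is the on-disk file size,
by definition), on image content, and on codebook overhead relative to
image size. The benchmark harness (`difftx_bench`) reports per-image and
min/mean/max aggregate ratios for any directory of real images the user
supplies.

## Raster formats

No image-decoding R packages are assumed: PNM (P2/P3/P5/P6, 16-bit
big-endian), PNG (gray/RGB, 8/16-bit, non-interlaced, all five scanline
filters on read, filter 0 on write), TIFF (uncompressed and deflate,
contiguous planar, either byte order on read) and BMP (24-bit BI_RGB) are
implemented directly, with zlib streams handled by base R's `memCompress`
machinery and CRC32 compiled. The readers are validated in the test suite
against files written by an independent implementation (Pillow), and the
writers by reading difftx-written files back through it. BMP cannot carry
16-bit or true single-channel data and says so (`capability` rather than
conversion); PNM round trips are byte-identical for canonical headers,
PNG/TIFF round trips sample-identical.

## Known limitations

* Huffman, not arithmetic/range coding: mean code length is within 1 bit
  of the stream entropy (asserted per stream), which is material for
  near-zero-entropy images where that bit is the whole payload.
* The per-file codebook is wasteful for very small or very noisy 16-bit
  images, where `(symbol, length)` entries can rival the payload.
* No interlaced, palette or alpha PNG; no LZW/JPEG TIFF; no DICOM.
* Single-threaded; images are held in memory (an H×W×C integer array).
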