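Package: difftx
Title: Lossless Image Compression with the Integer Difference Transform
Version: 0.1.0
Authors@R:
    person("difftx", "maintainers", email = "difftx@example.org", role = c("aut", "cre"))
Description: A complete, bit-exact lossless raster-image codec built on the
    integer Difference Transform: a three-tap prediction-residual transform
    that splits an image into a subsampled base and horizontal, vertical and
    diagonal detail planes, iterated into a multiresolution pyramid and
    entropy-coded with a canonical static Huffman code.  Includes readers and
    writers for PNM (PGM/PPM), PNG, TIFF and BMP rasters at 8 and 16 bits, a
    deterministic synthetic-fixture generator, a compression benchmark
    harness, and a command-line front end.  Every code path round-trips
    sample-exactly, which is the property the codec exists to guarantee.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
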