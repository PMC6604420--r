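Package: huffdicom
Title: Lossless Huffman Compression for DICOM Medical Image Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless compression and decompression of DICOM part-10 medical
    image files using static Huffman coding driven by the byte frequency
    distribution of the whole file. Provides byte-frequency profiling and
    entropy diagnostics, deterministic Huffman prefix-tree and canonical
    codeword construction, an MSB-first bit-packed container format (.huf)
    with a canonical code-length header, lookup-table decoding, compression
    ratio and space-savings reporting, a minimal DICOM parser with window
    level/width and nearest-neighbour resize for viewing decompressed
    images, and a deterministic synthetic DICOM generator for testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    png
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
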