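# .huf container layout (bit-exact):
#   magic "HUF1" (4) | version 0x01 (1) | original_length u64 LE (8) |
#   256 canonical codeword lengths, one byte each (0 = absent symbol) |
#   padding_bits (1) | bit-packed payload.
# Storing canonical lengths instead of the tree keeps the header at a fixed
# 270 bytes and guarantees the serialized form never reproduces the DICOM
# preamble+magic layout: byte offset 128 falls inside the length table.

HUF_MAGIC <- charToRaw("HUF1")
HUF_VERSION <- 1L
HUF_HEADER_BYTES <- 4L + 1L + 8L + 256L + 1L

#' Compress a byte stream into a Huffman container
#'
#' Runs the full encoding pipeline: byte frequency distribution, Huffman
#' prefix tree, codeword lengths, canonical code, bit-packed payload. The
#' payload is encoded with the canonical code rebuilt from the lengths (the
#' same code the decoder will reconstruct from the header).
#'
#' @param data Raw vector or file path; must be non-empty.
#' @return An object of class `huf_container`: list with `original_length`,
#'   `code_lengths` (integer vector of 256), and `payload`
#'   (an `encoded_payload`).
#' @export
compress_file <- function(data) {
  data <- as_bytes(data)
  if (length(data) == 0L) stop("nothing to encode: input is empty")
  bfd <- compute_bfd(data)
  tree <- build_tree(bfd)
  lengths <- canonical_lengths(assign_codewords(tree))
  if (any(lengths > 255L)) stop("codeword length exceeds 255 bits")
  code <- canonical_code_from_lengths(lengths)
  payload <- encode_payload(data, code)
  structure(
    list(original_length = length(data),
         code_lengths = lengths,
         payload = payload),
    class = "huf_container"
  )
}

#' Decompress a Huffman container
#'
#' Rebuilds the canonical code from the header's length table and decodes
#' the payload back to exactly `original_length` bytes. After the last
#' symbol the decoder verifies that all meaningful payload bits were
#' consumed, so a container whose header was tampered with fails loudly
#' instead of silently returning a stream of the wrong length.
#'
#' @param container A `huf_container`.
#' @return Raw vector identical to the pre-compression input.
#' @export
decompress_file <- function(container) {
  stopifnot(inherits(container, "huf_container"))
  # every codeword is at least one bit, so a valid container can never
  # declare more symbols than it has payload bits
  if (container$original_length > container$payload$payload_bits) {
    stop("corrupted stream: declared original length exceeds payload capacity")
  }
  code <- canonical_code_from_lengths(container$code_lengths)
  dec <- decode_bits_cpp(container$payload$payload_bytes, unclass(code),
                         as.numeric(container$original_length))
  if (dec$bits_consumed != container$payload$payload_bits) {
    stop("corrupted stream: payload bits left over after the declared ",
         "original length was reached")
  }
  dec$data
}

#' Serialize a container to its on-disk byte layout
#'
#' @param container A `huf_container`.
#' @return Raw vector: fixed 270-byte header followed by the payload.
#' @export
huf_serialize <- function(container) {
  stopifnot(inherits(container, "huf_container"))
  c(HUF_MAGIC,
    as.raw(HUF_VERSION),
    num_to_u64le(container$original_length),
    as.raw(container$code_lengths),
    as.raw(container$payload$padding_bits),
    container$payload$payload_bytes)
}

#' Parse serialized container bytes
#'
#' Validates the magic tag, format version, code-length table (Kraft
#' equality for two or more symbols, never above 1) and padding field;
#' each failure raises a distinct error.
#'
#' @param bytes Raw vector or file path.
#' @return A `huf_container`.
#' @export
huf_parse <- function(bytes) {
  bytes <- as_bytes(bytes)
  if (length(bytes) < HUF_HEADER_BYTES) stop("truncated container: no full header")
  if (!identical(bytes[1:4], HUF_MAGIC)) stop("bad magic: not a HUF1 container")
  if (as.integer(bytes[5]) != HUF_VERSION) {
    stop("unsupported container version: ", as.integer(bytes[5]))
  }
  original_length <- u64le_to_num(bytes[6:13])
  lengths <- as.integer(bytes[14:269])
  nz <- lengths[lengths > 0L]
  if (length(nz) == 0L) stop("invalid code lengths: no symbols")
  kr <- sum(2^-nz)
  if (kr > 1) stop("invalid code lengths: Kraft sum exceeds 1")
  if (length(nz) >= 2L && kr != 1) {
    stop("invalid code lengths: incomplete code (Kraft sum below 1)")
  }
  padding_bits <- as.integer(bytes[270])
  if (padding_bits > 7L) stop("invalid padding field: ", padding_bits)
  payload_bytes <- bytes[-seq_len(HUF_HEADER_BYTES)]
  payload_bits <- length(payload_bytes) * 8 - padding_bits
  if (length(payload_bytes) == 0L && padding_bits != 0L) {
    stop("invalid padding field: padding without payload")
  }
  if (original_length == 0) stop("invalid original length: 0")
  structure(
    list(original_length = original_length,
         code_lengths = lengths,
         payload = structure(list(payload_bytes = payload_bytes,
                                  payload_bits = payload_bits,
                                  padding_bits = padding_bits),
                             class = "encoded_payload")),
    class = "huf_container"
  )
}

#' @export
print.huf_container <- function(x, ...) {
  n_sym <- sum(x$code_lengths > 0L)
  comp <- HUF_HEADER_BYTES + length(x$payload$payload_bytes)
  cat("HUF1 compressed container\n")
  cat(sprintf("  original size:   %s bytes\n",
              format(x$original_length, big.mark = ",")))
  cat(sprintf("  compressed size: %s bytes (header %d + payload %s)\n",
              format(comp, big.mark = ","), HUF_HEADER_BYTES,
              format(length(x$payload$payload_bytes), big.mark = ",")))
  cat(sprintf("  symbols: %d, codeword lengths %d..%d, padding %d bit(s)\n",
              n_sym, min(x$code_lengths[x$code_lengths > 0L]),
              max(x$code_lengths), x$payload$padding_bits))
  invisible(x)
}

#' Check that a compressed file no longer looks like DICOM
#'
#' A part-10 DICOM file carries the ASCII magic "DICM" at byte offset 128
#' and UID strings with the "1.2.840" registry prefix early in the file;
#' both are what viewers and text editors key on. This check reports
#' whether a serialized container has obscured both landmarks.
#'
#' @param serialized Raw vector or file path of the serialized form.
#' @return Logical: `TRUE` iff bytes 128-131 (0-based) are not "DICM" and
#'   "1.2.840" does not occur in the first 1024 bytes. Attributes
#'   `dicm_at_128` and `uid_prefix_in_first_kb` carry the two sub-checks.
#' @export
check_obfuscation <- function(serialized) {
  bytes <- as_bytes(serialized)
  dicm <- length(bytes) >= 132L &&
    identical(bytes[129:132], charToRaw("DICM"))
  head_kb <- bytes[seq_len(min(1024L, length(bytes)))]
  uid <- length(grepRaw("1.2.840", head_kb, fixed = TRUE)) > 0L
  structure(!dicm && !uid, dicm_at_128 = dicm, uid_prefix_in_first_kb = uid)
}

#' Compress a file on disk to a .huf file
#'
#' @param input Path to the input file (typically a `.dcm`).
#' @param output Path for the compressed output; default swaps the
#'   extension for `.huf`.
#' @return Invisibly, the `huf_container`, with attributes `original_size`,
#'   `compressed_size` and `seconds` (wall-clock compression time).
#' @export
huf_compress <- function(input, output = swap_ext(input, "huf")) {
  data <- as_bytes(input)
  t0 <- proc.time()[["elapsed"]]
  container <- compress_file(data)
  bytes <- huf_serialize(container)
  seconds <- proc.time()[["elapsed"]] - t0
  writeBin(bytes, output)
  invisible(structure(container,
                      original_size = length(data),
                      compressed_size = length(bytes),
                      seconds = seconds))
}

#' Decompress a .huf file on disk
#'
#' @param input Path to the compressed `.huf` file.
#' @param output Path for the restored file; default swaps the extension
#'   for `.dcm`.
#' @return Invisibly, the restored raw bytes, with attribute `seconds`.
#' @export
huf_decompress <- function(input, output = swap_ext(input, "dcm")) {
  container <- huf_parse(input)
  t0 <- proc.time()[["elapsed"]]
  data <- decompress_file(container)
  seconds <- proc.time()[["elapsed"]] - t0
  writeBin(data, output)
  invisible(structure(data, seconds = seconds))
}

swap_ext <- function(path, ext) {
  paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".", ext)
}

num_to_u64le <- function(x) {
  stopifnot(x >= 0, x < 2^53)
  out <- raw(8)
  for (i in 1:8) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

u64le_to_num <- function(bytes) {
  sum(as.numeric(bytes) * 256^(0:7))
}
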