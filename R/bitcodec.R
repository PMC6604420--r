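#' Encode a byte stream into a bit-packed payload
#'
#' Substitutes each input byte with its codeword and concatenates the
#' codewords MSB-first into output bytes, appending zero bits after the last
#' codeword to reach the next byte boundary (bit padding). The padding is
#' inert at decode time because decoding stops after the original symbol
#' count.
#'
#' @param data Raw vector to encode (may be empty).
#' @param table A `huffman_code` covering every byte value occurring in
#'   `data`; an occurring byte without a codeword is an error naming the
#'   byte value.
#' @return An object of class `encoded_payload`: list with `payload_bytes`
#'   (raw), `payload_bits` (meaningful bits before padding) and
#'   `padding_bits` (0-7).
#' @export
encode_payload <- function(data, table) {
  stopifnot(is.raw(data), inherits(table, "huffman_code"))
  if (length(data) == 0L) {
    return(structure(list(payload_bytes = raw(0), payload_bits = 0,
                          padding_bits = 0L),
                     class = "encoded_payload"))
  }
  enc <- encode_bits_cpp(data, unclass(table))
  bits <- enc$payload_bits
  structure(
    list(payload_bytes = enc$payload_bytes,
         payload_bits = bits,
         padding_bits = as.integer((8 - bits %% 8) %% 8)),
    class = "encoded_payload"
  )
}

#' @export
print.encoded_payload <- function(x, ...) {
  cat(sprintf("Encoded payload: %s bits (+%d padding) in %s bytes\n",
              format(x$payload_bits, big.mark = ","), x$padding_bits,
              format(length(x$payload_bytes), big.mark = ",")))
  invisible(x)
}

#' Build the decode lookup table
#'
#' Inverts a codeword table into a codeword-to-symbol map, the structure the
#' decoder consults while threading bits off the compressed stream.
#'
#' @param table A `huffman_code`.
#' @return An object of class `decode_lookup`: a named integer vector,
#'   names are codeword bitstrings, values the byte values they decode to.
#' @export
build_lookup <- function(table) {
  stopifnot(inherits(table, "huffman_code"))
  codes <- unclass(table)
  present <- which(!is.na(codes))
  lookup <- present - 1L
  names(lookup) <- codes[present]
  structure(lookup, class = "decode_lookup")
}

#' @export
print.decode_lookup <- function(x, ...) {
  cat(sprintf("Decode lookup table: %d codewords\n", length(x)))
  invisible(x)
}

#' Decode a bit-packed payload back to bytes
#'
#' Reads the payload bit by bit, walking the prefix tree implied by the
#' lookup table from the root until a codeword completes, emitting its
#' symbol, and restarting — until `original_length` symbols have been
#' produced. Padding bits are never interpreted. A bit thread that leaves
#' the code, or a stream that ends early, raises a corruption error.
#'
#' @param payload An `encoded_payload` (or a raw vector of payload bytes).
#' @param lookup A `decode_lookup`.
#' @param original_length Number of bytes to emit (the pre-compression
#'   length).
#' @return Raw vector of exactly `original_length` bytes.
#' @export
decode_payload <- function(payload, lookup, original_length) {
  stopifnot(inherits(lookup, "decode_lookup"))
  bytes <- if (inherits(payload, "encoded_payload")) payload$payload_bytes
           else as_bytes(payload)
  if (original_length < 0) stop("original_length must be non-negative")
  if (original_length == 0) return(raw(0))
  codes <- rep(NA_character_, 256L)
  codes[unclass(lookup) + 1L] <- names(lookup)
  dec <- decode_bits_cpp(bytes, codes, as.numeric(original_length))
  dec$data
}

#' Incremental-prefix reference decoder
#'
#' A deliberately simple second implementation of payload decoding: the bit
#' thread is grown one bit at a time and looked up as a string in the
#' codeword-to-symbol map after every bit. Used to cross-check the tree-walk
#' decoder; quadratic in codeword length, so only suitable for small inputs.
#'
#' @inheritParams decode_payload
#' @return Raw vector of exactly `original_length` bytes.
#' @export
decode_payload_incremental <- function(payload, lookup, original_length) {
  stopifnot(inherits(lookup, "decode_lookup"))
  bytes <- if (inherits(payload, "encoded_payload")) payload$payload_bytes
           else as_bytes(payload)
  if (original_length == 0) return(raw(0))
  map <- new.env(parent = emptyenv())
  for (i in seq_along(lookup)) assign(names(lookup)[i], lookup[[i]], envir = map)
  max_len <- max(nchar(names(lookup)))
  bits <- as.integer(rawToBits(bytes))           # LSB-first per byte
  if (length(bits)) {
    bits <- as.vector(matrix(bits, nrow = 8L)[8:1, ])  # MSB-first per byte
  }
  out <- raw(original_length)
  thread <- character(0)
  k <- 0L
  for (b in bits) {
    thread <- c(thread, as.character(b))
    key <- paste(thread, collapse = "")
    if (!is.null(sym <- map[[key]])) {
      k <- k + 1L
      out[k] <- as.raw(sym)
      thread <- character(0)
      if (k == original_length) return(out)
    } else if (length(thread) >= max_len) {
      stop("corrupted stream: bit thread matches no codeword")
    }
  }
  stop("corrupted stream: bits exhausted before all symbols were decoded")
}
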