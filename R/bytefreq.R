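#' Byte frequency distribution of a byte stream
#'
#' Tallies the occurrences of each of the 256 possible byte values over an
#' entire file or in-memory buffer. The whole stream is profiled, including
#' the DICOM preamble and "DICM" magic when the input is a part-10 file: the
#' static Huffman code built downstream covers every byte of the file, which
#' is also what renders the compressed file unreadable as DICOM.
#'
#' @param data A raw vector, or the path to a file to profile.
#' @return An object of class `byte_freq`: a list with `counts`, a numeric
#'   vector of length 256 (element `i` is the count of byte value `i - 1`),
#'   and `total_bytes`, the length of the profiled input. An empty input is
#'   valid and yields all-zero counts.
#' @examples
#' bfd <- compute_bfd(as.raw(c(0xFF, 0xFF, 0x00)))
#' bfd$counts[256]  # occurrences of byte 0xFF
#' @export
compute_bfd <- function(data) {
  data <- as_bytes(data)
  counts <- tabulate(as.integer(data) + 1L, nbins = 256L)
  structure(
    list(counts = as.numeric(counts), total_bytes = length(data)),
    class = "byte_freq"
  )
}

#' Build a byte_freq object from explicit counts
#'
#' Convenience constructor used when the distribution is known directly
#' (e.g. frequency tables quoted from compression reports) rather than
#' tallied from a stream.
#'
#' @param counts Numeric vector of non-negative counts. Either length 256
#'   (positional, byte value = index - 1) or shorter, in which case
#'   `symbols` gives the byte values the counts belong to.
#' @param symbols Optional integer vector of byte values (0-255) matching
#'   `counts` when `counts` is not length 256.
#' @return A `byte_freq` object.
#' @export
byte_freq <- function(counts, symbols = NULL) {
  if (is.null(symbols)) {
    if (length(counts) != 256L) {
      stop("`counts` must have length 256 when `symbols` is not given")
    }
    full <- as.numeric(counts)
  } else {
    if (length(symbols) != length(counts)) {
      stop("`symbols` and `counts` must have the same length")
    }
    check_symbols(symbols)
    full <- numeric(256L)
    full[symbols + 1L] <- as.numeric(counts)
  }
  if (any(is.na(full)) || any(full < 0) || any(full != floor(full))) {
    stop("counts must be non-negative integers")
  }
  structure(list(counts = full, total_bytes = sum(full)), class = "byte_freq")
}

#' @export
print.byte_freq <- function(x, ...) {
  nz <- sum(x$counts > 0)
  cat("Byte frequency distribution\n")
  cat(sprintf("  total bytes: %s\n", format(x$total_bytes, big.mark = ",")))
  cat(sprintf("  distinct byte values: %d of 256\n", nz))
  if (nz > 0) {
    top <- order(x$counts, decreasing = TRUE)[seq_len(min(5L, nz))]
    cat("  most frequent:",
        paste(sprintf("0x%02X (%s)", top - 1L,
                      format(x$counts[top], big.mark = ",", trim = TRUE)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Distribution diagnostics for a byte frequency table
#'
#' Summarises how evenly a byte distribution spreads: the number of distinct
#' byte values present, the empirical Shannon entropy in bits per byte, and
#' an evenness index (entropy divided by its maximum `log2(n_symbols)`).
#' A file whose distribution concentrates on a few byte values (low entropy)
#' compresses well under Huffman coding; a near-uniform distribution
#' (entropy close to 8 bits/byte, evenness close to 1) does not compress and
#' can even expand.
#'
#' @param bfd A `byte_freq` object.
#' @return A list of class `byte_freq_stats` with `n_symbols`,
#'   `entropy_bits_per_byte` and `evenness`. An empty distribution yields
#'   `n_symbols = 0`, entropy 0 and evenness 1; so does a single-symbol
#'   distribution (evenness is defined as 1 when `n_symbols <= 1`).
#' @export
distribution_stats <- function(bfd) {
  stopifnot(inherits(bfd, "byte_freq"))
  counts <- bfd$counts
  total <- bfd$total_bytes
  nz <- counts[counts > 0]
  n_symbols <- length(nz)
  if (total == 0 || n_symbols == 0L) {
    out <- list(n_symbols = 0L, entropy_bits_per_byte = 0, evenness = 1)
  } else {
    p <- nz / total
    entropy <- -sum(p * log2(p))
    entropy <- max(entropy, 0)  # guard tiny negative rounding
    evenness <- if (n_symbols <= 1L) 1 else entropy / log2(n_symbols)
    out <- list(n_symbols = n_symbols,
                entropy_bits_per_byte = entropy,
                evenness = min(evenness, 1))
  }
  structure(out, class = "byte_freq_stats")
}

#' @export
print.byte_freq_stats <- function(x, ...) {
  cat(sprintf("symbols: %d, entropy: %.4f bits/byte, evenness: %.4f\n",
              x$n_symbols, x$entropy_bits_per_byte, x$evenness))
  invisible(x)
}

# Coerce a file path or raw vector to raw bytes.
as_bytes <- function(data) {
  if (is.raw(data)) return(data)
  if (is.character(data) && length(data) == 1L) {
    if (!file.exists(data)) stop("file not found: ", data)
    return(readBin(data, "raw", n = file.size(data)))
  }
  stop("`data` must be a raw vector or a single file path")
}

check_symbols <- function(symbols) {
  if (any(is.na(symbols)) || any(symbols < 0) || any(symbols > 255) ||
      any(symbols != floor(symbols))) {
    stop("symbols must be integers in 0..255")
  }
  if (anyDuplicated(symbols)) stop("symbols must be distinct")
  invisible(symbols)
}
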