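# Deterministic synthetic inputs. CT DICOM files compress well under a
# whole-file Huffman code because their byte distribution concentrates on a
# dominant value (large uniform background regions); scanned projections
# with near-uniform byte spread do not compress and can expand. The
# generators below reproduce both regimes with a controllable byte
# distribution, so no external image archive is needed.

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a pseudorandom byte stream with a prescribed distribution
#'
#' @param size_bytes Number of bytes to generate (0 is valid).
#' @param dist One of `"uniform"` (all 256 byte values equally likely,
#'   emulating incompressible near-uniform files), `"dominant_byte"` (one
#'   byte value takes `dominant_fraction` of the stream, the rest spread
#'   uniformly — the distribution shape of typical CT files), or
#'   `"custom"` (explicit 256-entry weight vector).
#' @param seed Integer seed; identical arguments and seed give a
#'   byte-identical stream, and the caller's RNG state is untouched.
#' @param dominant_fraction Expected share of the dominant byte, default
#'   0.63 (the share of the dominant byte in a benchmark CT file).
#' @param dominant_value The dominant byte value, default 0.
#' @param weights Non-negative 256-entry weight vector with positive sum,
#'   for `dist = "custom"`.
#' @return Raw vector of `size_bytes` bytes.
#' @export
generate_bytes <- function(size_bytes,
                           dist = c("dominant_byte", "uniform", "custom"),
                           seed = 1L,
                           dominant_fraction = 0.63,
                           dominant_value = 0L,
                           weights = NULL) {
  dist <- match.arg(dist)
  if (size_bytes < 0) stop("size_bytes must be non-negative")
  if (size_bytes == 0) return(raw(0))
  w <- switch(dist,
    uniform = rep(1, 256),
    dominant_byte = {
      if (dominant_fraction <= 0 || dominant_fraction >= 1) {
        stop("dominant_fraction must be in (0, 1)")
      }
      check_symbols(dominant_value)
      w <- rep((1 - dominant_fraction) / 255, 256)
      w[dominant_value + 1L] <- dominant_fraction
      w
    },
    custom = {
      if (is.null(weights) || length(weights) != 256L) {
        stop("`weights` must be a 256-entry vector for dist = \"custom\"")
      }
      if (any(is.na(weights)) || any(weights < 0) || sum(weights) <= 0) {
        stop("invalid weights: must be non-negative with positive sum")
      }
      weights
    }
  )
  with_seed(seed, {
    as.raw(sample.int(256L, size_bytes, replace = TRUE, prob = w) - 1L)
  })
}

#' Generate a minimal valid DICOM part-10 file
#'
#' Builds an explicit-VR little-endian part-10 stream: 128-byte zero
#' preamble, "DICM" magic, a minimal file-meta group (including the
#' transfer syntax UID), the image-pixel module tags and native pixel data
#' whose bytes follow the prescribed distribution. Header bytes are a small
#' fixed overhead, mirroring real files where pixel data dominates the byte
#' distribution. The output parses with [parse_dicom()].
#'
#' @param rows,cols Frame dimensions, positive integers.
#' @param n_frames Number of frames, positive integer.
#' @param bits_allocated 8 or 16 bits per sample.
#' @param window_center,window_width Optional windowing hints embedded as
#'   DICOM elements.
#' @inheritParams generate_bytes
#' @return Raw vector holding the complete part-10 file.
#' @export
generate_dicom <- function(rows = 64L, cols = 64L, n_frames = 1L,
                           bits_allocated = 16L,
                           dist = c("dominant_byte", "uniform", "custom"),
                           seed = 1L,
                           dominant_fraction = 0.63,
                           dominant_value = 0L,
                           weights = NULL,
                           window_center = NULL, window_width = NULL) {
  if (rows < 1 || cols < 1 || n_frames < 1) {
    stop("invalid geometry: rows, cols and n_frames must be positive")
  }
  if (!bits_allocated %in% c(8L, 16L)) {
    stop("bits_allocated must be 8 or 16")
  }
  n_pixel_bytes <- rows * cols * n_frames * (bits_allocated %/% 8L)
  pixel_raw <- generate_bytes(n_pixel_bytes, dist = dist, seed = seed,
                              dominant_fraction = dominant_fraction,
                              dominant_value = dominant_value,
                              weights = weights)
  dcm_assemble(as.integer(rows), as.integer(cols), as.integer(n_frames),
               as.integer(bits_allocated), pixel_raw,
               window_center = window_center, window_width = window_width)
}

#' Worked-example fixtures
#'
#' In-memory fixtures for the arithmetic worked through in compression
#' reports, available without any randomness:
#'
#' * `hex_excerpt` — the 80-byte opening of a CT DICOM file (preamble tail,
#'   "DICM" magic at offset 16, first file-meta bytes, 16-bit samples).
#' * `eq1`, `eq2` — partial byte-frequency tables of two benchmark CT
#'   files: `symbols` (byte values 0x00, 0x03, 0xFE), `counts`, and the
#'   assumed codeword `lengths` (2, 5, 6) whose weighted sums give the
#'   predicted payload sizes 1,597,918 and 1,398,276 bits.
#' * `equal8` — a 40-byte stream of 8 distinct symbols ("A".."H"), 5
#'   occurrences each: the equal-frequency limit where Huffman coding
#'   yields uniform 3-bit codewords and no compression.
#'
#' @return Named list of fixtures; deterministic, no seed involved.
#' @export
worked_example_fixtures <- function() {
  hex <- c(
    "00 00 00 00 00 00 00 00 00 00 00 00 00 00 00 00",
    "44 49 43 4d 02 00 00 00 55 4c 04 00 be 00 00 00",
    "82 04 82 04 82 04 82 04 82 04 82 04 82 04 82 04",
    "7d 04 78 04 78 04 78 04 78 04 78 04 69 04 5a 04",
    "5a 04 00 00 00 00 00 00 00 00 00 00 00 00 00 00"
  )
  hex_excerpt <- as.raw(strtoi(unlist(strsplit(hex, " ")), 16L))
  list(
    hex_excerpt = hex_excerpt,
    eq1 = list(symbols = c(0x00, 0x03, 0xFE),
               counts = c(663477, 24806, 24489),
               lengths = c(2L, 5L, 6L)),
    eq2 = list(symbols = c(0x00, 0x03, 0xFE),
               counts = c(698830, 14, 91),
               lengths = c(2L, 5L, 6L)),
    equal8 = as.raw(rep(65:72, times = 5))
  )
}
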