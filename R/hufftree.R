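#' Build a Huffman prefix tree from a byte frequency distribution
#'
#' Classical static Huffman construction: every byte value with a nonzero
#' count becomes a leaf weighted by its count, and the two minimum-weight
#' nodes are merged repeatedly until one root remains. Frequent bytes end up
#' near the root and so receive short codewords.
#'
#' Ties are broken deterministically: merge candidates are ordered by
#' (weight, lowest byte value contained in the subtree), and the
#' lower-ordered node becomes the left (0-labelled) child. Any consistent
#' tie rule yields a code with the same codeword lengths; this one makes the
#' exact codewords reproducible across runs and platforms.
#'
#' @param bfd A `byte_freq` object with at least one nonzero count.
#' @return An object of class `huffman_tree`: a list with `root` (nested
#'   nodes; leaves carry `symbol`, internal nodes carry `left`/`right`,
#'   all carry `weight`), `leaf_count`, `node_count` and `depth`.
#' @export
build_tree <- function(bfd) {
  stopifnot(inherits(bfd, "byte_freq"))
  counts <- bfd$counts
  symbols <- which(counts > 0) - 1L
  if (length(symbols) == 0L) stop("nothing to encode: all byte frequencies are zero")

  nodes <- lapply(symbols, function(s) {
    list(weight = counts[s + 1L], symbol = s, min_symbol = s)
  })
  while (length(nodes) > 1L) {
    w <- vapply(nodes, function(n) n$weight, numeric(1))
    m <- vapply(nodes, function(n) n$min_symbol, numeric(1))
    ord <- order(w, m)
    a <- nodes[[ord[1L]]]
    b <- nodes[[ord[2L]]]
    merged <- list(weight = a$weight + b$weight,
                   left = a, right = b,
                   min_symbol = min(a$min_symbol, b$min_symbol))
    nodes <- c(nodes[-ord[1:2]], list(merged))
  }
  root <- nodes[[1L]]
  lc <- length(symbols)
  structure(
    list(root = root,
         leaf_count = lc,
         node_count = 2L * lc - 1L,
         depth = tree_depth(root)),
    class = "huffman_tree"
  )
}

tree_depth <- function(node) {
  if (!is.null(node$symbol)) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' @export
print.huffman_tree <- function(x, ...) {
  cat(sprintf("Huffman prefix tree: %d leaves, %d nodes, depth %d\n",
              x$leaf_count, x$node_count, x$depth))
  invisible(x)
}

#' Derive codewords from a Huffman prefix tree
#'
#' Walks the tree from the root, labelling left branches 0 and right
#' branches 1; the codeword of a symbol is the label path to its leaf. A
#' single-leaf tree gets the 1-bit codeword "0" so that its payload length
#' is well defined.
#'
#' @param tree A `huffman_tree`.
#' @return An object of class `huffman_code`: a character vector of length
#'   256 of "0"/"1" strings, `NA` for byte values absent from the source
#'   distribution, with attribute `max_length`.
#' @export
assign_codewords <- function(tree) {
  stopifnot(inherits(tree, "huffman_tree"))
  codes <- rep(NA_character_, 256L)
  walk <- function(node, prefix) {
    if (!is.null(node$symbol)) {
      codes[node$symbol + 1L] <<- if (nzchar(prefix)) prefix else "0"
    } else {
      walk(node$left, paste0(prefix, "0"))
      walk(node$right, paste0(prefix, "1"))
    }
  }
  walk(tree$root, "")
  new_huffman_code(codes)
}

new_huffman_code <- function(codes) {
  lens <- ifelse(is.na(codes), 0L, nchar(codes))
  structure(codes, max_length = max(lens), class = "huffman_code")
}

#' @export
print.huffman_code <- function(x, ...) {
  present <- which(!is.na(unclass(x)))
  cat(sprintf("Huffman code: %d symbols, codeword lengths %d..%d\n",
              length(present),
              if (length(present)) min(nchar(x[present])) else 0L,
              attr(x, "max_length")))
  if (length(present)) {
    show <- utils::head(present, 8L)
    for (i in show) cat(sprintf("  0x%02X -> %s\n", i - 1L, x[i]))
    if (length(present) > 8L) cat("  ...\n")
  }
  invisible(x)
}

#' Per-symbol codeword lengths
#'
#' Reduces a codeword table to the 256-entry vector of codeword lengths
#' (0 for byte values with no codeword). Under the canonical-code
#' convention this length table fully determines a decodable code, which is
#' what the `.huf` container header stores.
#'
#' @param table A `huffman_code`.
#' @return Integer vector of length 256.
#' @export
canonical_lengths <- function(table) {
  stopifnot(inherits(table, "huffman_code"))
  codes <- unclass(table)
  ifelse(is.na(codes), 0L, nchar(codes))
}

#' Reconstruct the canonical code from codeword lengths
#'
#' Symbols are ordered by (codeword length, byte value) and assigned
#' consecutive binary codewords, left-padding with zeros as the length
#' grows. Codeword assignment is exact bit arithmetic (no float), so
#' arbitrary lengths round-trip.
#'
#' @param lengths Integer vector of length 256; entry `i` is the codeword
#'   length of byte value `i - 1`, 0 meaning absent.
#' @return A `huffman_code` with the canonical codewords.
#' @export
canonical_code_from_lengths <- function(lengths) {
  if (length(lengths) != 256L) stop("`lengths` must have length 256")
  lengths <- as.integer(lengths)
  if (any(is.na(lengths)) || any(lengths < 0L)) stop("invalid codeword lengths")
  present <- which(lengths > 0L)
  codes <- rep(NA_character_, 256L)
  if (length(present) == 0L) return(new_huffman_code(codes))
  ord <- present[order(lengths[present], present)]
  # running codeword as a 0/1 integer vector: exact binary increment/extend
  bits <- integer(0)
  prev_len <- 0L
  for (s in ord) {
    len <- lengths[s]
    if (prev_len == 0L) {
      bits <- integer(len)                   # first codeword: all zeros
    } else {
      bits <- bits_increment(bits)
      if (len > prev_len) bits <- c(bits, integer(len - prev_len))
    }
    if (length(bits) > len) stop("invalid codeword lengths: Kraft sum exceeds 1")
    codes[s] <- paste(bits, collapse = "")
    prev_len <- len
  }
  new_huffman_code(codes)
}

# binary increment of a 0/1 vector, MSB first; grows on overflow
bits_increment <- function(bits) {
  i <- length(bits)
  while (i >= 1L && bits[i] == 1L) {
    bits[i] <- 0L
    i <- i - 1L
  }
  if (i == 0L) c(1L, bits) else { bits[i] <- 1L; bits }
}

#' Kraft sum of a codeword table
#'
#' @param table A `huffman_code`.
#' @return `sum(2^-length)` over the codewords present. Equals 1 for a
#'   complete prefix code over two or more symbols.
#' @export
kraft_sum <- function(table) {
  lens <- canonical_lengths(table)
  sum(2^-lens[lens > 0])
}

#' Predicted compressed payload size in bits
#'
#' The exact unpadded bit length of the encoded stream: the sum over byte
#' values of occurrence count times codeword length.
#'
#' @param bfd A `byte_freq` object.
#' @param table A `huffman_code` covering every byte value with a nonzero
#'   count in `bfd`.
#' @return Number of payload bits (numeric, exact integer value).
#' @export
predicted_payload_bits <- function(bfd, table) {
  stopifnot(inherits(bfd, "byte_freq"), inherits(table, "huffman_code"))
  lens <- canonical_lengths(table)
  missing <- which(bfd$counts > 0 & lens == 0L)
  if (length(missing)) {
    stop(sprintf("no codeword for occurring byte value(s): %s",
                 paste(sprintf("0x%02X", missing - 1L), collapse = ", ")))
  }
  sum(bfd$counts * lens)
}
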