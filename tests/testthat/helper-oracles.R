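# Independent oracles used across the suite.

# Exhaustive search over all integer codeword-length vectors satisfying the
# Kraft inequality: the minimum weighted bit count any prefix-free code can
# achieve for these counts. Tractable for up to ~6 symbols.
brute_optimal_bits <- function(counts) {
  k <- length(counts)
  if (k == 1L) return(counts)  # single symbol: 1-bit codeword
  maxlen <- k - 1L
  grid <- as.matrix(expand.grid(rep(list(seq_len(maxlen)), k)))
  ok <- rowSums(2^-grid) <= 1
  min(grid[ok, , drop = FALSE] %*% counts)
}

# Direct Shannon entropy of a count vector, bits per symbol.
entropy_oracle <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Prefix-freeness check by pairwise startsWith.
is_prefix_free <- function(codewords) {
  n <- length(codewords)
  if (n <= 1L) return(TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (startsWith(codewords[i], codewords[j]) ||
          startsWith(codewords[j], codewords[i])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

random_bytes <- function(n, alphabet = 0:255) {
  as.raw(sample(alphabet, n, replace = TRUE))
}

# build the Huffman code of a raw stream in one step
code_of <- function(data) {
  assign_codewords(build_tree(compute_bfd(data)))
}
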