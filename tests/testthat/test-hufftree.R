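test_that("tree shape invariants hold for equal-frequency alphabets", {
  # 8 symbols, equal frequency: perfectly balanced tree, all leaves at depth 3
  t8 <- build_tree(byte_freq(rep(5, 8), symbols = 65:72))
  expect_equal(t8$leaf_count, 8L)
  expect_equal(t8$node_count, 15L)
  expect_equal(t8$depth, 3L)
  cw8 <- assign_codewords(t8)
  lens8 <- canonical_lengths(cw8)
  expect_true(all(lens8[66:73] == 3L))
  expect_setequal(unclass(cw8)[66:73],
                  apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = ""))

  # 256 symbols, equal frequency: all leaves at depth 8, 511 nodes
  t256 <- build_tree(byte_freq(rep(1, 256)))
  expect_equal(t256$depth, 8L)
  expect_equal(t256$node_count, 511L)
  expect_true(all(canonical_lengths(assign_codewords(t256)) == 8L))
})

test_that("skewed frequencies give the known optimal depth profile", {
  # counts {5,2,1,1}: leaf depths {1,2,3,3}, weighted path length 15 bits
  bfd <- byte_freq(c(5, 2, 1, 1), symbols = 0:3)
  cw <- assign_codewords(build_tree(bfd))
  lens <- canonical_lengths(cw)[1:4]
  expect_equal(sort(lens), c(1L, 2L, 3L, 3L))
  expect_equal(predicted_payload_bits(bfd, cw), 15)
  expect_equal(brute_optimal_bits(c(5, 2, 1, 1)), 15)
})

test_that("degenerate and error cases behave as specified", {
  expect_error(build_tree(compute_bfd(raw(0))), "nothing to encode")
  # single symbol: 1-bit codeword "0"
  cw1 <- assign_codewords(build_tree(byte_freq(10, symbols = 42)))
  expect_equal(unclass(cw1)[43], "0")
  expect_equal(canonical_lengths(cw1)[43], 1L)
  # two symbols: the only prefix-free pair
  cw2 <- assign_codewords(build_tree(byte_freq(c(3, 1), symbols = c(10, 20))))
  expect_setequal(unclass(cw2)[c(11, 21)], c("0", "1"))
})

test_that("codeword tables are prefix-free with Kraft equality", {
  set.seed(101)
  for (rep in 1:25) {
    k <- sample(2:256, 1)
    symbols <- sort(sample(0:255, k))
    counts <- sample(1:5000, k, replace = TRUE)
    cw <- assign_codewords(build_tree(byte_freq(counts, symbols = symbols)))
    present <- unclass(cw)[!is.na(unclass(cw))]
    expect_length(present, k)
    expect_true(is_prefix_free(present))
    expect_equal(kraft_sum(cw), 1)
    # strictly more frequent symbols never get longer codewords
    lens <- canonical_lengths(cw)[symbols + 1L]
    expect_false(any(outer(counts, counts, ">") & outer(lens, lens, ">")))
  }
})

test_that("Huffman codes are optimal among all prefix codes (<= 6 symbols)", {
  set.seed(202)
  cases <- list(c(1, 1), c(5, 2, 1, 1), c(1, 1, 1, 1, 1, 1))
  for (k in 2:6) {
    for (i in 1:10) cases <- c(cases, list(sample(1:500, k, replace = TRUE)))
  }
  for (counts in cases) {
    k <- length(counts)
    bfd <- byte_freq(counts, symbols = seq_len(k) - 1L)
    cw <- assign_codewords(build_tree(bfd))
    expect_equal(predicted_payload_bits(bfd, cw), brute_optimal_bits(counts))
  }
})

test_that("payload bits sit in the entropy sandwich", {
  set.seed(303)
  for (rep in 1:20) {
    k <- sample(2:200, 1)
    counts <- sample(1:2000, k, replace = TRUE)
    bfd <- byte_freq(counts, symbols = seq_len(k) - 1L)
    bits <- predicted_payload_bits(bfd, assign_codewords(build_tree(bfd)))
    n <- sum(counts)
    h <- entropy_oracle(counts)
    expect_gte(bits, n * h - 1e-6)
    expect_lte(bits, n * (h + 1) + 1e-6)
  }
})

test_that("merge replay confirms the sibling property", {
  # replay the greedy merges on the multiset of leaf weights: at each step
  # the two smallest weights must be the ones combined
  set.seed(404)
  counts <- sample(1:100, 40, replace = TRUE)
  tree <- build_tree(byte_freq(counts, symbols = seq_len(40) - 1L))
  merged_pairs <- list()
  collect <- function(node) {
    if (is.null(node$symbol)) {
      merged_pairs[[length(merged_pairs) + 1L]] <<-
        sort(c(node$left$weight, node$right$weight))
      collect(node$left)
      collect(node$right)
    }
  }
  collect(tree$root)
  # weights of merged pairs, replayed smallest-first, must match a fresh
  # greedy simulation on the weight multiset
  sim <- sort(counts)
  replay <- list()
  pool <- counts
  while (length(pool) > 1) {
    pool <- sort(pool)
    replay[[length(replay) + 1L]] <- pool[1:2]
    pool <- c(pool[-(1:2)], sum(pool[1:2]))
  }
  expect_setequal(
    vapply(merged_pairs, paste, character(1), collapse = ","),
    vapply(replay, paste, character(1), collapse = ",")
  )
})

test_that("canonical lengths round-trip through canonical codewords", {
  set.seed(505)
  for (rep in 1:10) {
    k <- sample(1:256, 1)
    symbols <- sort(sample(0:255, k))
    counts <- sample(1:999, k, replace = TRUE)
    lens <- canonical_lengths(assign_codewords(build_tree(
      byte_freq(counts, symbols = symbols))))
    canon <- canonical_code_from_lengths(lens)
    expect_equal(canonical_lengths(canon), lens)
    present <- unclass(canon)[!is.na(unclass(canon))]
    expect_true(is_prefix_free(present))
    expect_false(anyDuplicated(present) > 0)
  }
  # over-subscribed lengths are rejected
  bad <- integer(256); bad[1:3] <- 1L
  expect_error(canonical_code_from_lengths(bad), "Kraft")
})

test_that("predicted payload bits reproduce the worked frequency sums", {
  fx <- worked_example_fixtures()
  for (eq in list(fx$eq1, fx$eq2)) {
    bfd <- byte_freq(eq$counts, symbols = eq$symbols)
    lens <- integer(256)
    lens[eq$symbols + 1L] <- eq$lengths
    code <- canonical_code_from_lengths(lens)
    expect_equal(predicted_payload_bits(bfd, code), sum(eq$counts * eq$lengths))
  }
  expect_error(
    predicted_payload_bits(byte_freq(c(1, 1), symbols = c(0, 9)),
                           canonical_code_from_lengths(
                             `[<-`(integer(256), 1, 1L))),
    "no codeword")
  expect_equal(predicted_payload_bits(compute_bfd(raw(0)),
                                      canonical_code_from_lengths(
                                        `[<-`(integer(256), 1, 1L))),
               0)
})
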