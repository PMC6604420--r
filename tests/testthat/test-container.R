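test_that("compress/serialize/parse/decompress is the identity", {
  set.seed(13)
  inputs <- c(
    lapply(1:15, function(i) random_bytes(sample(1:2000, 1))),
    list(as.raw(0), as.raw(rep(7, 1000)), worked_example_fixtures()$hex_excerpt,
         generate_dicom(rows = 16, cols = 16, n_frames = 3, seed = 5))
  )
  for (data in inputs) {
    ser <- huf_serialize(compress_file(data))
    expect_identical(decompress_file(huf_parse(ser)), data)
  }
  expect_error(compress_file(raw(0)), "empty")
})

test_that("serialized size equals header plus ceil(payload bits / 8)", {
  set.seed(14)
  for (rep in 1:10) {
    data <- random_bytes(sample(10:5000, 1))
    container <- compress_file(data)
    ser <- huf_serialize(container)
    bits <- predicted_payload_bits(compute_bfd(data),
                                   canonical_code_from_lengths(container$code_lengths))
    expect_equal(length(ser), 270 + ceiling(bits / 8))
  }
})

test_that("parse validates each header field with a distinct error", {
  data <- generate_bytes(500, seed = 2)
  ser <- huf_serialize(compress_file(data))
  # round trip field-for-field
  expect_equal(huf_parse(ser), compress_file(data))

  bad_magic <- ser; bad_magic[1] <- as.raw(0x58)
  expect_error(huf_parse(bad_magic), "bad magic")
  bad_ver <- ser; bad_ver[5] <- as.raw(9)
  expect_error(huf_parse(bad_ver), "unsupported container version")
  bad_pad <- ser; bad_pad[270] <- as.raw(8)
  expect_error(huf_parse(bad_pad), "invalid padding")
  expect_error(huf_parse(ser[1:100]), "truncated")
  no_sym <- ser; no_sym[14:269] <- raw(256)
  expect_error(huf_parse(no_sym), "no symbols")
})

test_that("single-symbol container round-trips", {
  data <- as.raw(rep(0xAB, 37))
  ser <- huf_serialize(compress_file(data))
  container <- huf_parse(ser)
  expect_equal(sum(container$code_lengths > 0), 1)
  expect_identical(decompress_file(container), data)
})

test_that("header tampering fails loudly, never a silently wrong length", {
  data <- generate_bytes(800, dist = "dominant_byte", seed = 3)
  ser <- huf_serialize(compress_file(data))
  # flip every bit of the fixed header in turn
  for (byte_i in 1:270) {
    for (bit in c(1L, 8L)) {  # lowest and highest bit of each header byte
      tampered <- ser
      tampered[byte_i] <- xor(tampered[byte_i], as.raw(bitwShiftL(1L, bit - 1L)))
      out <- tryCatch(decompress_file(huf_parse(tampered)),
                      error = function(e) e)
      # either a loud, clean error, or the emitted length still matches
      expect_true(inherits(out, "error") || length(out) == length(data))
    }
  }
})

test_that("payload tampering is detected or length-preserving, never a crash", {
  data <- generate_bytes(600, dist = "dominant_byte", seed = 4)
  ser <- huf_serialize(compress_file(data))
  set.seed(15)
  for (rep in 1:30) {
    i <- sample(271:length(ser), 1)
    tampered <- ser
    tampered[i] <- xor(tampered[i], as.raw(sample(0:7, 1) + 1))
    out <- tryCatch(decompress_file(huf_parse(tampered)), error = function(e) e)
    expect_true(inherits(out, "error") || length(out) == length(data))
  }
})

test_that("compressed output hides the DICOM landmarks", {
  dcm <- generate_dicom(rows = 32, cols = 32, n_frames = 2, seed = 21)
  # negative control: the original is recognisable DICOM
  expect_identical(dcm[129:132], charToRaw("DICM"))
  expect_false(isTRUE(check_obfuscation(dcm)))
  ser <- huf_serialize(compress_file(dcm))
  ob <- check_obfuscation(ser)
  expect_true(isTRUE(ob))
  expect_false(attr(ob, "dicm_at_128"))
  expect_false(attr(ob, "uid_prefix_in_first_kb"))
})

test_that("near-uniform input expands (compression ratio below 1)", {
  data <- generate_bytes(20000, dist = "uniform", seed = 8)
  ser <- huf_serialize(compress_file(data))
  expect_gt(length(ser), length(data))
  expect_lt(compression_ratio(length(data), length(ser)), 1)
})

test_that("dominant-byte input compresses well below its original size", {
  data <- generate_bytes(50000, dist = "dominant_byte", seed = 9,
                         dominant_fraction = 0.63)
  ser <- huf_serialize(compress_file(data))
  expect_lt(length(ser), length(data))
  # entropy bound: payload cannot beat n*H, and here n*H << n*8
  st <- distribution_stats(compute_bfd(data))
  expect_gte(length(ser) * 8, 50000 * st$entropy_bits_per_byte)
})

test_that("file-level compress/decompress wrappers round-trip on disk", {
  dir <- tempfile("hufio")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  dcm <- file.path(dir, "fixture.dcm")
  writeBin(generate_dicom(rows = 24, cols = 24, n_frames = 2, seed = 33), dcm)
  huf <- file.path(dir, "fixture.huf")
  out <- file.path(dir, "restored.dcm")
  huf_compress(dcm, huf)
  huf_decompress(huf, out)
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(dcm, "raw", file.size(dcm)))
})
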