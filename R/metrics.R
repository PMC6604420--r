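#' Compression ratio
#'
#' The ratio original size / compressed size, the "1 : r" figure quoted in
#' compression benchmarks. A ratio above 1 means the file shrank; a ratio
#' below 1 means the compressed file is larger than the original, which
#' static Huffman coding produces on near-uniform byte distributions.
#'
#' @param original_size,compressed_size Sizes in bytes, both positive.
#' @return The ratio at full precision (reports round it to 4 decimals).
#' @export
compression_ratio <- function(original_size, compressed_size) {
  if (original_size <= 0) stop("original_size must be positive")
  if (compressed_size <= 0) stop("compressed_size must be positive")
  original_size / compressed_size
}

#' Space savings percentage
#'
#' `100 * (1 - compressed/original)`: positive exactly when the compression
#' ratio exceeds 1, negative when the file expanded.
#'
#' @inheritParams compression_ratio
#' @return Savings in percent, full precision (reports round to 2 decimals).
#' @export
space_savings <- function(original_size, compressed_size) {
  if (original_size <= 0) stop("original_size must be positive")
  100 * (1 - compressed_size / original_size)
}

# round half away from zero, matching the table conventions of
# compression benchmarks (R's round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Batch compression report
#'
#' Compresses each file, decompresses it again, verifies the round trip and
#' tabulates sizes, symbol counts, compression ratio, space savings and
#' wall-clock timings. Timing columns are informational only: they depend
#' on the machine and are not comparable across hosts. An unreadable file
#' produces a row with the error message in `status` and the batch
#' continues.
#'
#' @param files Character vector of file paths.
#' @return A data frame of class `compression_report` with one row per
#'   file: `file_name`, `original_size`, `compressed_size`, `n_symbols`,
#'   `ratio` (rounded to 4 decimals), `space_savings_pct` (rounded to 2),
#'   `compress_seconds`, `decompress_seconds`, `status` ("ok" or an error
#'   message).
#' @export
batch_report <- function(files) {
  rows <- lapply(files, function(path) {
    res <- tryCatch({
      data <- as_bytes(path)
      t0 <- proc.time()[["elapsed"]]
      container <- compress_file(data)
      bytes <- huf_serialize(container)
      t_comp <- proc.time()[["elapsed"]] - t0
      t0 <- proc.time()[["elapsed"]]
      restored <- decompress_file(huf_parse(bytes))
      t_dec <- proc.time()[["elapsed"]] - t0
      if (!identical(restored, data)) stop("round trip mismatch")
      data.frame(
        file_name = basename(path),
        original_size = length(data),
        compressed_size = length(bytes),
        n_symbols = sum(container$code_lengths > 0L),
        ratio = round_half_up(compression_ratio(length(data), length(bytes)), 4),
        space_savings_pct =
          round_half_up(space_savings(length(data), length(bytes)), 2),
        compress_seconds = t_comp,
        decompress_seconds = t_dec,
        status = "ok",
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      data.frame(file_name = basename(path), original_size = NA_real_,
                 compressed_size = NA_real_, n_symbols = NA_integer_,
                 ratio = NA_real_, space_savings_pct = NA_real_,
                 compress_seconds = NA_real_, decompress_seconds = NA_real_,
                 status = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("compression_report", "data.frame")
  out
}

#' @export
print.compression_report <- function(x, ...) {
  cat("Compression report (timings are machine-dependent)\n")
  df <- as.data.frame(x)
  df$ratio <- ifelse(is.na(df$ratio), NA,
                     sprintf("1 : %.4f", df$ratio))
  print(df, row.names = FALSE)
  invisible(x)
}
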