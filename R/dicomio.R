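# Minimal DICOM part-10 reader/writer: explicit-VR little-endian only,
# native (uncompressed) pixel data only. This is the surface the viewer and
# the synthetic generator need; it is not a general DICOM toolkit.

VR_LONG_FORM <- c("OB", "OW", "OF", "SQ", "UT", "UN")
VR_SHORT_FORM <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD",
                   "IS", "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM",
                   "UI", "UL", "US")

u16le <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256))
u32le <- function(x) {
  out <- raw(4)
  for (i in 1:4) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# one explicit-VR little-endian data element
dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
      value <- c(value, pad)
    }
  }
  head <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% VR_LONG_FORM) {
    c(head, raw(2), u32le(length(value)), value)
  } else {
    if (length(value) > 65535L) stop("value too long for short-form VR")
    c(head, u16le(length(value)), value)
  }
}

# Assemble a part-10 stream: preamble, magic, file-meta group, dataset.
dcm_assemble <- function(rows, cols, n_frames, bits_allocated, pixel_raw,
                         window_center = NULL, window_width = NULL) {
  ts_uid <- "1.2.840.10008.1.2.1"  # explicit VR little endian
  meta_body <- c(
    dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_element(0x0002, 0x0003, "UI", "1.2.840.10008.99.999.1"),
    dcm_element(0x0002, 0x0010, "UI", ts_uid)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", u32le(length(meta_body))),
            meta_body)
  pixel_vr <- if (bits_allocated == 8L) "OB" else "OW"
  dataset <- c(
    dcm_element(0x0008, 0x0060, "CS", "CT"),
    dcm_element(0x0028, 0x0002, "US", u16le(1L)),
    dcm_element(0x0028, 0x0008, "IS", as.character(n_frames)),
    dcm_element(0x0028, 0x0010, "US", u16le(rows)),
    dcm_element(0x0028, 0x0011, "US", u16le(cols)),
    dcm_element(0x0028, 0x0100, "US", u16le(bits_allocated)),
    dcm_element(0x0028, 0x0101, "US", u16le(bits_allocated)),
    dcm_element(0x0028, 0x0102, "US", u16le(bits_allocated - 1L)),
    dcm_element(0x0028, 0x0103, "US", u16le(0L))
  )
  if (!is.null(window_center)) {
    dataset <- c(dataset,
                 dcm_element(0x0028, 0x1050, "DS", format(window_center)))
  }
  if (!is.null(window_width)) {
    dataset <- c(dataset,
                 dcm_element(0x0028, 0x1051, "DS", format(window_width)))
  }
  dataset <- c(dataset, dcm_element(0x7FE0, 0x0010, pixel_vr, pixel_raw))
  c(raw(128), charToRaw("DICM"), meta, dataset)
}

read_u16le <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}
read_u32le <- function(bytes, pos) {
  sum(as.numeric(bytes[pos:(pos + 3L)]) * 256^(0:3))
}

#' Parse a DICOM part-10 file
#'
#' Reads the 128-byte preamble, verifies the "DICM" magic, walks the
#' explicit-VR little-endian data elements, and extracts the image-pixel
#' module: dimensions, frame count, bit depth, windowing hints and the pixel
#' samples themselves. Only native (uncompressed) pixel data is supported.
#'
#' @param data Raw vector or file path.
#' @return An object of class `dicom_image`: list with `rows`, `cols`,
#'   `n_frames`, `bits_allocated`, `pixel_frames` (a list of
#'   rows-by-cols integer matrices, one per frame), `window_center`,
#'   `window_width` (or `NULL`) and `metadata` (named list of tag keyed
#'   element values for display).
#' @export
parse_dicom <- function(data) {
  bytes <- as_bytes(data)
  if (length(bytes) < 132L || !identical(bytes[129:132], charToRaw("DICM"))) {
    stop("not a DICOM part-10 file: missing DICM magic at offset 128")
  }
  pos <- 133L
  n <- length(bytes)
  metadata <- list()
  pixel_raw <- NULL
  while (pos + 7L <= n) {
    group <- read_u16le(bytes, pos)
    elem <- read_u16le(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% VR_LONG_FORM) {
      len <- read_u32le(bytes, pos + 8L)
      val_start <- pos + 12L
    } else if (vr %in% VR_SHORT_FORM) {
      len <- read_u16le(bytes, pos + 6L)
      val_start <- pos + 8L
    } else {
      stop(sprintf("cannot parse element (%04X,%04X): unknown VR '%s'",
                   group, elem, vr))
    }
    if (val_start + len - 1L > n) stop("truncated DICOM element")
    value <- if (len > 0) bytes[val_start:(val_start + len - 1L)] else raw(0)
    key <- sprintf("(%04X,%04X)", group, elem)
    if (group == 0x7FE0 && elem == 0x0010) {
      pixel_raw <- value
      metadata[[key]] <- sprintf("<pixel data, %d bytes>", len)
    } else {
      metadata[[key]] <- decode_element(vr, value)
    }
    pos <- val_start + len
  }
  rows <- metadata[["(0028,0010)"]]
  cols <- metadata[["(0028,0011)"]]
  bits <- metadata[["(0028,0100)"]]
  if (is.null(rows) || is.null(cols) || is.null(bits)) {
    stop("missing image pixel module (rows/columns/bits allocated)")
  }
  if (is.null(pixel_raw)) stop("missing pixel data element (7FE0,0010)")
  n_frames <- if (!is.null(metadata[["(0028,0008)"]])) {
    as.integer(metadata[["(0028,0008)"]])
  } else 1L
  bytes_per <- bits %/% 8L
  expected <- rows * cols * n_frames * bytes_per
  if (length(pixel_raw) != expected) {
    stop(sprintf("pixel data size mismatch: %d bytes, expected %d",
                 length(pixel_raw), expected))
  }
  samples <- if (bytes_per == 1L) {
    as.integer(pixel_raw)
  } else {
    readBin(pixel_raw, "integer", n = length(pixel_raw) %/% 2L,
            size = 2L, signed = FALSE, endian = "little")
  }
  per_frame <- rows * cols
  pixel_frames <- lapply(seq_len(n_frames), function(f) {
    fr <- samples[((f - 1L) * per_frame + 1L):(f * per_frame)]
    matrix(fr, nrow = rows, ncol = cols, byrow = TRUE)
  })
  wc <- metadata[["(0028,1050)"]]
  ww <- metadata[["(0028,1051)"]]
  structure(
    list(rows = rows, cols = cols, n_frames = n_frames,
         bits_allocated = bits, pixel_frames = pixel_frames,
         window_center = if (!is.null(wc)) as.numeric(wc) else NULL,
         window_width = if (!is.null(ww)) as.numeric(ww) else NULL,
         metadata = metadata),
    class = "dicom_image"
  )
}

decode_element <- function(vr, value) {
  if (vr %in% c("UI", "CS", "LO", "PN", "SH", "DA", "TM", "AE", "AS",
                "DT", "LT", "ST", "UT")) {
    sub("[\\x00 ]+$", "", rawToChar(value), perl = TRUE)
  } else if (vr %in% c("IS", "DS")) {
    trimws(rawToChar(value))
  } else if (vr == "US") {
    read_u16le(value, 1L)
  } else if (vr == "UL") {
    read_u32le(value, 1L)
  } else {
    value
  }
}

#' @export
print.dicom_image <- function(x, ...) {
  cat(sprintf("DICOM image: %d x %d, %d frame(s), %d bits/sample\n",
              x$rows, x$cols, x$n_frames, x$bits_allocated))
  if (!is.null(x$window_center)) {
    cat(sprintf("  window center/width: %g / %g\n",
                x$window_center, x$window_width))
  }
  cat(sprintf("  %d metadata elements\n", length(x$metadata)))
  invisible(x)
}
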