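#' Linear window level/width mapping to 8-bit grayscale
#'
#' Applies the standard linear value-of-interest transform used by CT
#' viewers: samples at or below `center - width/2` map to 0 (black),
#' samples at or above `center + width/2` map to 255 (white), and the span
#' in between maps linearly. Rounding is half-up, so a sample exactly at
#' the window center maps to 128.
#'
#' @param frame Integer or numeric matrix of raw samples.
#' @param center Window center (level), in sample units.
#' @param width Window width, in sample units; must be positive.
#' @return Integer matrix of the same shape with values in 0..255.
#' @export
apply_window <- function(frame, center, width) {
  if (!is.matrix(frame)) stop("`frame` must be a matrix")
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    stop("window width must be a single positive number")
  }
  out <- floor((frame - (center - width / 2)) / width * 255 + 0.5)
  out <- pmin(pmax(out, 0), 255)
  storage.mode(out) <- "integer"
  out
}

#' Nearest-neighbour resize of an image frame
#'
#' Resamples a frame to the requested dimensions by nearest-neighbour
#' pixel-centre mapping: deterministic, exactly invertible for integer
#' upscaling, and value-preserving (no new sample values are invented).
#'
#' @param frame Matrix of samples.
#' @param out_rows,out_cols Target dimensions, both at least 1.
#' @return Matrix of dimension `out_rows` by `out_cols`.
#' @export
resize <- function(frame, out_rows, out_cols) {
  if (!is.matrix(frame)) stop("`frame` must be a matrix")
  if (out_rows < 1 || out_cols < 1) stop("target dimensions must be positive")
  ri <- nn_index(nrow(frame), out_rows)
  ci <- nn_index(ncol(frame), out_cols)
  frame[ri, ci, drop = FALSE]
}

nn_index <- function(n_in, n_out) {
  idx <- ceiling((seq_len(n_out) - 0.5) * n_in / n_out)
  pmin(pmax(idx, 1L), n_in)
}

#' Render one frame of a DICOM image to a grayscale array or PNG
#'
#' Convenience wrapper around frame selection, windowing and resizing —
#' the "View" pipeline. If the image carries no window hints and none are
#' given, a full-range window over the frame's min..max is used.
#'
#' @param image A `dicom_image` from [parse_dicom()].
#' @param frame 1-based frame index.
#' @param center,width Window parameters; default to the image's stored
#'   hints, then to the frame's full sample range.
#' @param out_rows,out_cols Optional target dimensions for resizing.
#' @param png_path If given, the 8-bit frame is also written there as PNG.
#' @return Integer matrix of 8-bit grayscale values, invisibly when
#'   `png_path` is given.
#' @export
view_frame <- function(image, frame = 1L, center = NULL, width = NULL,
                       out_rows = NULL, out_cols = NULL, png_path = NULL) {
  stopifnot(inherits(image, "dicom_image"))
  if (frame < 1L || frame > image$n_frames) {
    stop(sprintf("frame %d out of range 1..%d", frame, image$n_frames))
  }
  fr <- image$pixel_frames[[frame]]
  if (is.null(center)) center <- image$window_center
  if (is.null(width)) width <- image$window_width
  if (is.null(center) || is.null(width)) {
    lo <- min(fr)
    hi <- max(fr)
    center <- (lo + hi) / 2
    width <- max(hi - lo, 1)
  }
  out <- apply_window(fr, center, width)
  if (!is.null(out_rows) || !is.null(out_cols)) {
    out <- resize(out,
                  if (is.null(out_rows)) nrow(out) else out_rows,
                  if (is.null(out_cols)) ncol(out) else out_cols)
  }
  if (!is.null(png_path)) {
    png::writePNG(out / 255, png_path)
    return(invisible(out))
  }
  out
}
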