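#' Time-lapse frame container
#'
#' A frame is one grayscale intensity grid with values in `[0, 1]` plus its
#' index in the acquisition sequence and its acquisition time in minutes.
#' Pixel coordinates follow the R matrix convention used throughout the
#' package: `y` is the row index and `x` the column index, both 1-based,
#' with the origin at the top-left pixel centre.
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`. A 3-channel
#'   array is converted to grayscale with [rgb_to_gray()].
#' @param frame_index 0-based index of the frame in its sequence.
#' @param time_min acquisition time in minutes.
#' @return An object of class `spheromon_frame`.
#' @examples
#' f <- new_frame(matrix(0.5, 10, 10), frame_index = 0, time_min = 0)
#' dim(f$pixels)
#' @export
new_frame <- function(pixels, frame_index = 0L, time_min = 0) {
  if (is.array(pixels) && length(dim(pixels)) == 3L)
    pixels <- rgb_to_gray(pixels)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("frame intensities must be finite")
  if (any(pixels < 0) || any(pixels > 1))
    stop("frame intensities must lie in [0, 1]")
  structure(
    list(pixels = pixels, frame_index = as.integer(frame_index),
         time_min = as.numeric(time_min)),
    class = "spheromon_frame")
}

#' @export
print.spheromon_frame <- function(x, ...) {
  cat(sprintf("<spheromon_frame> %d x %d px, index %d, t = %g min\n",
              nrow(x$pixels), ncol(x$pixels), x$frame_index, x$time_min))
  invisible(x)
}

# accept either a frame or a bare matrix
frame_pixels <- function(frame) {
  if (inherits(frame, "spheromon_frame")) frame$pixels
  else if (is.matrix(frame)) frame
  else stop("expected a spheromon_frame or a numeric matrix")
}

#' Convert an RGB array to grayscale
#'
#' Uses the Rec.601 luma weighting `0.299 R + 0.587 G + 0.114 B`, the
#' convention used for intensity analysis of colour-camera acquisitions.
#'
#' @param arr numeric array `rows x cols x 3` with values in `[0, 1]`.
#' @return A numeric matrix of the same spatial size.
#' @export
rgb_to_gray <- function(arr) {
  if (length(dim(arr)) != 3L || dim(arr)[3] != 3L)
    stop("`arr` must be rows x cols x 3")
  arr[, , 1] * 0.299 + arr[, , 2] * 0.587 + arr[, , 3] * 0.114
}
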