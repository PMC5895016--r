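#' Construct a video tensor
#'
#' A `video_tensor` is the in-memory representation of a video used throughout
#' the package: an ordered stack of frames with a known sampling rate. Frames
#' are stored as a 4-D numeric array with dimensions height x width x channels
#' x time, and intensities live on the real-valued \[0, 1\] scale. Values are
#' allowed to leave \[0, 1\] transiently during processing (magnification can
#' overshoot); clipping happens only at 8-bit export.
#'
#' @param frames Numeric array. Either H x W (single gray frame stack of 1 is
#'   not allowed; T >= 2), H x W x T (grayscale) or H x W x C x T with C in
#'   {1, 3}.
#' @param fps Sampling rate in Hz (frames per second); must be > 0.
#' @param colorspace `"gray"` or `"rgb"`. Inferred from the channel count when
#'   missing.
#' @return An object of class `video_tensor` with elements `frames` (H x W x
#'   C x T array), `fps` and `colorspace`.
#' @examples
#' v <- video_tensor(array(runif(16 * 16 * 5), c(16, 16, 5)), fps = 10)
#' dim(v$frames)
#' @export
video_tensor <- function(frames, fps, colorspace = NULL) {
  if (!is.numeric(frames)) stop("frames must be a numeric array")
  d <- dim(frames)
  if (is.null(d) || length(d) < 3L || length(d) > 4L)
    stop("frames must be an H x W x T or H x W x C x T array")
  if (length(d) == 3L) {
    # interpret as grayscale H x W x T
    frames <- array(frames, c(d[1], d[2], 1L, d[3]))
    d <- dim(frames)
  }
  if (!(d[3] %in% c(1L, 3L))) stop("channel count must be 1 or 3")
  if (d[4] < 2L) stop("a video must have T >= 2 frames")
  if (d[1] < 8L || d[2] < 8L) stop("frames must be at least 8 x 8 pixels")
  if (!all(is.finite(frames))) stop("all intensities must be finite")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number")
  if (is.null(colorspace)) colorspace <- if (d[3] == 3L) "rgb" else "gray"
  colorspace <- match.arg(colorspace, c("rgb", "gray"))
  if (colorspace == "rgb" && d[3] != 3L)
    stop("rgb colorspace requires 3 channels")
  structure(list(frames = frames, fps = as.numeric(fps),
                 colorspace = colorspace),
            class = "video_tensor")
}

#' @export
print.video_tensor <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_tensor> %d x %d px, %d channel(s), %d frames @ %g fps (%.1f s)\n",
              d[1], d[2], d[3], d[4], x$fps, d[4] / x$fps))
  invisible(x)
}

#' @export
dim.video_tensor <- function(x) dim(x$frames)

#' Number of frames in a video
#' @param video A `video_tensor`.
#' @return Integer frame count T.
#' @export
n_frames <- function(video) dim(video$frames)[4]

#' Convert a video to grayscale
#'
#' RGB frames are reduced with the Rec. 601 luma weights
#' (0.299, 0.587, 0.114); grayscale input is returned unchanged.
#'
#' @param video A `video_tensor`.
#' @return A grayscale `video_tensor`.
#' @export
to_gray <- function(video) {
  stopifnot(inherits(video, "video_tensor"))
  if (video$colorspace == "gray") return(video)
  f <- video$frames
  g <- 0.299 * f[, , 1, , drop = FALSE] + 0.587 * f[, , 2, , drop = FALSE] +
    0.114 * f[, , 3, , drop = FALSE]
  video_tensor(g, video$fps, "gray")
}

# Quantize intensities to the 8-bit grid, clipping to [0, 1] first.
# Internal: used at export and by tests that need bit-exact round trips.
quantize8 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  round(x * 255) / 255
}
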