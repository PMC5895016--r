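#' Read a video from a lossless PNG frame sequence
#'
#' The canonical on-disk format is a directory of zero-padded PNG frames
#' (`frame_000001.png`, ...) together with a JSON sidecar `fps.json`
#' containing `{"fps": <Hz>}`. This path is codec-free and bit-exact, which
#' is what the verification suite relies on. Compressed containers (MP4/AVI)
#' are not supported by this build and raise an error.
#'
#' @param path Directory containing the PNG sequence and `fps.json`.
#' @param as_gray Collapse RGB input to grayscale on read.
#' @param fps Sampling rate override in Hz; when `NULL` the sidecar is used.
#' @return A [video_tensor()].
#' @seealso [write_video()]
#' @export
read_video <- function(path, as_gray = FALSE, fps = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (!dir.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("mp4", "avi", "mov", "mkv"))
      stop("compressed video containers are not supported; ",
           "use a PNG frame sequence directory (see write_video)")
    stop("path must be a directory containing a PNG frame sequence")
  }
  pngs <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(pngs) == 0L) stop("no PNG frames found in ", path)
  if (is.null(fps)) {
    sidecar <- file.path(path, "fps.json")
    if (!file.exists(sidecar))
      stop("no fps.json sidecar in ", path, " and no fps= override given")
    fps <- jsonlite::fromJSON(sidecar)$fps
  }
  first <- png::readPNG(pngs[1])
  hw <- dim(first)[1:2]
  nc <- if (length(dim(first)) == 2L) 1L else dim(first)[3]
  if (nc == 4L) nc <- 3L  # drop alpha
  if (nc == 2L) nc <- 1L  # gray + alpha
  frames <- array(0, c(hw[1], hw[2], nc, length(pngs)))
  for (t in seq_along(pngs)) {
    img <- png::readPNG(pngs[t])
    if (!identical(dim(img)[1:2], hw))
      stop("frame ", t, " has mismatched dimensions")
    if (length(dim(img)) == 2L) {
      frames[, , 1, t] <- img
    } else {
      frames[, , , t] <- img[, , seq_len(nc)]
    }
  }
  v <- video_tensor(frames, fps = fps)
  if (as_gray) v <- to_gray(v)
  v
}

#' Write a video as a lossless PNG frame sequence
#'
#' Writes zero-padded 8-bit PNG frames plus an `fps.json` sidecar. Intensities
#' are clipped to \[0, 1\] and quantized to the 8-bit grid at this point only;
#' in-memory processing never clips. A tensor already on the 8-bit grid
#' round-trips bit-exactly through [read_video()].
#'
#' @param video A [video_tensor()].
#' @param path Output directory (created if needed).
#' @param lossless Must be `TRUE`; lossy container export is not available in
#'   this build.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path, lossless = TRUE) {
  stopifnot(inherits(video, "video_tensor"))
  if (!isTRUE(lossless))
    stop("lossy container export is not supported; use lossless = TRUE")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("could not create output directory ", path)
  d <- dim(video$frames)
  for (t in seq_len(d[4])) {
    img <- quantize8(video$frames[, , , t])
    if (d[3] == 1L) img <- matrix(img, d[1], d[2])
    png::writePNG(img, file.path(path, sprintf("frame_%06d.png", t)))
  }
  jsonlite::write_json(list(fps = video$fps),
                       file.path(path, "fps.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Validate a configuration against the Nyquist criterion
#'
#' The temporal sampling theorem requires the frame rate to exceed twice the
#' highest temporal frequency of interest: magnifying a passband reaching
#' `f_h` Hz is only meaningful when `f_h < fps / 2`.
#'
#' @param f_l,f_h Temporal passband edges in Hz.
#' @param fps Video frame rate in Hz.
#' @return Invisibly `TRUE` on success; otherwise an error describing the
#'   minimum frame rate required.
#' @examples
#' validate_nyquist(0.2, 0.3, fps = 50)
#' @export
validate_nyquist <- function(f_l, f_h, fps) {
  if (!is.finite(f_l) || f_l <= 0) stop("f_l must be positive")
  if (!is.finite(f_h) || f_h <= f_l) stop("f_h must exceed f_l")
  if (f_h >= fps / 2)
    stop(sprintf(paste0("passband upper edge f_h = %g Hz violates the ",
                        "Nyquist criterion at fps = %g Hz; a frame rate ",
                        "above %g Hz is required"),
                 f_h, fps, 2 * f_h))
  invisible(TRUE)
}
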