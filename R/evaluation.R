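# Quality metrics, pixel traces, the sub-pixel displacement oracle and
# respiration-rate estimation.

check_same_shape <- function(a, b) {
  if (!all(dim(a$frames) == dim(b$frames)))
    stop("videos must have identical dimensions")
}

#' Mean squared error between two videos
#'
#' Computed on the 0-255 intensity scale: per frame and channel the mean of
#' squared differences, channel MSEs averaged (the arithmetic mean over R, G
#' and B for color input), then averaged over frames.
#'
#' @param original,magnified [video_tensor()]s of identical shape.
#' @return A `quality_report`: list with `mse`, `psnr` (dB),
#'   `per_channel_mse` and `frame_psnr`.
#' @export
video_mse <- function(original, magnified) {
  check_same_shape(original, magnified)
  d <- dim(original$frames)
  diff2 <- (255 * (original$frames - magnified$frames))^2
  per_channel <- apply(diff2, 3, mean)
  frame_mse <- apply(diff2, 4, mean)
  mse <- mean(per_channel)
  structure(list(mse = mse,
                 psnr = mse_to_psnr(mse),
                 per_channel_mse = per_channel,
                 frame_psnr = mse_to_psnr(frame_mse)),
            class = "quality_report")
}

mse_to_psnr <- function(mse) ifelse(mse > 0, 10 * log10(255^2 / mse), Inf)

#' Peak signal-to-noise ratio between two videos
#'
#' `PSNR = 10 * log10(255^2 / MSE)` in dB (log base 10, as the dB definition
#' requires). Identical videos give `Inf` ("identical"). PSNR has no absolute
#' meaning here; it is used to compare the effect of alpha across methods.
#'
#' @inheritParams video_mse
#' @return PSNR in dB.
#' @export
video_psnr <- function(original, magnified) video_mse(original, magnified)$psnr

#' @export
print.quality_report <- function(x, ...) {
  if (is.infinite(x$psnr)) cat("<quality_report> identical videos (MSE 0)\n")
  else cat(sprintf("<quality_report> MSE %.4f (0-255 scale), PSNR %.2f dB\n",
                   x$mse, x$psnr))
  invisible(x)
}

#' Intensity trace of one pixel over time
#'
#' Returns the per-frame intensity at a pixel/channel on the 0-255 scale —
#' the raw material of before/after magnification comparisons.
#'
#' @param video A [video_tensor()].
#' @param x Column (1-based), `y` row, `channel` 1-based channel index or one
#'   of `"r"`, `"g"`, `"b"`.
#' @param y,channel See `x`.
#' @return A `motion_trace`: list with `values` (length T), `fps`, `source`.
#' @export
pixel_trace <- function(video, x, y, channel = 1L) {
  stopifnot(inherits(video, "video_tensor"))
  d <- dim(video$frames)
  if (is.character(channel))
    channel <- match(tolower(channel), c("r", "g", "b"))
  if (is.na(channel) || channel < 1L || channel > d[3])
    stop("channel out of range")
  if (x < 1L || x > d[2] || y < 1L || y > d[1])
    stop("pixel coordinate out of bounds")
  structure(list(values = 255 * video$frames[y, x, channel, ],
                 fps = video$fps,
                 source = list(x = x, y = y, channel = channel)),
            class = "motion_trace")
}

# --- sub-pixel displacement oracle ------------------------------------------

# Single-frame 2-D shift estimate by cross-correlation in the Fourier domain
# with local DFT upsampling (matrix-multiply refinement around the integer
# peak). weight = "magnitude" keeps the spectral energy weighting (matched
# filter; robust when the scene is smooth and high frequencies carry no
# signal); "phase" whitens the cross-power spectrum (classic phase
# correlation).
phasecorr_shift <- function(ref, img, upsample = 100L, eps = 1e-6,
                            weight = c("magnitude", "phase")) {
  weight <- match.arg(weight)
  F0 <- stats::fft(ref)
  Ft <- stats::fft(img)
  C <- Ft * Conj(F0)
  if (weight == "phase") {
    mag <- Mod(C)
    C <- C / (mag + eps * max(mag))
  }
  C[1, 1] <- 0  # constant background carries no motion information
  cc <- stats::fft(C, inverse = TRUE)
  p <- which.max(Mod(cc)) - 1L
  n <- dim(ref)
  py <- p %% n[1]; px <- p %/% n[1]
  if (py > n[1] / 2) py <- py - n[1]
  if (px > n[2] / 2) px <- px - n[2]
  # refine on a +-1 px window at 1/upsample resolution
  wy <- fft_freqs(n[1]); wx <- fft_freqs(n[2])
  uy <- py + seq(-1, 1, by = 1 / upsample)
  ux <- px + seq(-1, 1, by = 1 / upsample)
  Ey <- exp(1i * outer(uy, wy))       # length(uy) x n1
  Ex <- exp(1i * outer(wx, ux))       # n2 x length(ux)
  cc_fine <- Ey %*% C %*% Ex
  pk <- arrayInd(which.max(Mod(cc_fine)), dim(cc_fine))
  c(dy = uy[pk[1]], dx = ux[pk[2]])
}

#' Measure per-frame sub-pixel translation of a region
#'
#' The independent motion oracle: for every frame, the translation of the
#' region relative to frame 1 is estimated by Fourier-domain correlation with
#' upsampled (matrix-DFT) peak refinement, to about 0.01 px. The region must
#' contain texture; the constant (DC) component is ignored, so a uniform
#' background does not bias the estimate. The default spectral weighting is
#' the cross-correlation (matched filter); `weight = "phase"` switches to the
#' whitened cross-power spectrum of classic phase correlation, which weights
#' all frequencies equally and is noisier on smooth scenes.
#'
#' @param video A [video_tensor()] (RGB input is collapsed to gray).
#' @param roi Optional region `list(x = c(x0, x1), y = c(y0, y1))`; default
#'   is the full frame.
#' @param axis `"x"`, `"y"` or `"both"`; for `"both"` the values are the
#'   signed displacement magnitude projected on the dominant axis.
#' @param weight Spectral weighting, `"magnitude"` or `"phase"`.
#' @return A `motion_trace` with `values` in px (length T) and `dx`, `dy`
#'   components.
#' @export
measure_displacement <- function(video, roi = NULL, axis = c("x", "y", "both"),
                                 weight = c("magnitude", "phase")) {
  axis <- match.arg(axis)
  weight <- match.arg(weight)
  g <- to_gray(video)
  fr <- g$frames
  d <- dim(fr)
  if (is.null(roi)) roi <- list(x = c(1L, d[2]), y = c(1L, d[1]))
  ys <- roi$y[1]:roi$y[2]; xs <- roi$x[1]:roi$x[2]
  ref <- fr[ys, xs, 1, 1]
  if (stats::var(as.vector(ref)) == 0)
    stop("ROI has no texture (zero intensity variance)")
  T_ <- d[4]
  dx <- numeric(T_); dy <- numeric(T_)
  for (t in seq(2L, T_)) {
    s <- phasecorr_shift(ref, fr[ys, xs, 1, t], weight = weight)
    dy[t] <- s["dy"]; dx[t] <- s["dx"]
  }
  values <- switch(axis, x = dx, y = dy, both = {
    if (sum(abs(dx)) >= sum(abs(dy))) dx else dy
  })
  structure(list(values = values, fps = video$fps, dx = dx, dy = dy,
                 source = list(roi = roi, axis = axis)),
            class = "motion_trace")
}

#' Amplitude of a periodic component in a trace
#'
#' Least-squares fit of `a cos + b sin` at a known frequency (plus an
#' intercept); returns `sqrt(a^2 + b^2)`. Used to turn displacement traces
#' into motion amplitudes when the ground-truth frequency is known.
#'
#' @param trace A `motion_trace` or numeric vector.
#' @param freq Frequency in Hz.
#' @param fps Sampling rate (taken from the trace when available).
#' @return Amplitude in the trace's units.
#' @export
trace_amplitude <- function(trace, freq, fps = NULL) {
  if (inherits(trace, "motion_trace")) {
    fps <- trace$fps
    v <- trace$values
  } else v <- as.numeric(trace)
  if (is.null(fps)) stop("fps required for a bare numeric trace")
  tt <- (seq_along(v) - 1) / fps
  X <- cbind(1, cos(2 * pi * freq * tt), sin(2 * pi * freq * tt))
  cf <- stats::lm.fit(X, v)$coefficients
  unname(sqrt(cf[2]^2 + cf[3]^2))
}

#' Estimate the respiration rate from a motion trace
#'
#' Detrended, cosine-tapered periodogram restricted to the physiological band
#' 0.1-0.5 Hz (6-30 breaths/min). The peak is reported only when its power
#' exceeds `prominence` times the median in-band power; otherwise the result
#' is "no respiration detected".
#'
#' @param trace A `motion_trace` or numeric vector.
#' @param fps Sampling rate in Hz (taken from the trace when available).
#' @param band Search band in Hz.
#' @param prominence Peak-to-median power ratio required for detection.
#' @return A `breath_rate`: list with `detected`, `freq_hz`, `bpm`.
#' @export
estimate_breath_rate <- function(trace, fps = NULL, band = c(0.1, 0.5),
                                 prominence = 4) {
  if (inherits(trace, "motion_trace")) {
    fps <- trace$fps
    v <- trace$values
  } else v <- as.numeric(trace)
  if (is.null(fps)) stop("fps required for a bare numeric trace")
  n <- length(v)
  if (n / fps < 20) stop("trace too short: need at least 20 s of samples")
  if (stats::sd(v) < 1e-12)  # flat trace: nothing to detect
    return(structure(list(detected = FALSE, freq_hz = NA_real_,
                          bpm = NA_real_), class = "breath_rate"))
  tt <- seq_len(n)
  v <- stats::residuals(stats::lm.fit(cbind(1, tt), v))  # mean + linear detrend
  taper <- 0.5 * (1 - cos(2 * pi * (tt - 1) / (n - 1)))  # Hann
  pw <- Mod(stats::fft(v * taper))^2
  f <- (seq_len(n) - 1) * fps / n
  inband <- which(f >= band[1] & f <= band[2])
  if (length(inband) < 3L) stop("frequency resolution too coarse for the band")
  pin <- pw[inband]
  med <- stats::median(pin)
  pk <- which.max(pin)
  detected <- med > 0 && pin[pk] >= prominence * med
  structure(list(detected = detected,
                 freq_hz = if (detected) f[inband[pk]] else NA_real_,
                 bpm = if (detected) 60 * f[inband[pk]] else NA_real_),
            class = "breath_rate")
}

#' @export
print.breath_rate <- function(x, ...) {
  if (!x$detected) cat("<breath_rate> no respiration detected\n")
  else cat(sprintf("<breath_rate> %.3f Hz = %.1f breaths/min\n",
                   x$freq_hz, x$bpm))
  invisible(x)
}
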