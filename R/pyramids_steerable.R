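# Complex steerable pyramid, constructed in the frequency domain.
#
# The spectrum is partitioned by raised-cosine (in log-radius) radial windows
# and cos^(K-1) angular windows supported on a half-plane, so band
# coefficients are complex (analytic) and carry a local amplitude and phase.
# Scale s is decimated by cropping the centered spectrum, which is lossless
# on the band's support. The filter set tiles the spectrum exactly:
# H0^2 + sum_s,k (M_sk^2 + M_sk(-u)^2) + L^2 = 1, so reconstruction is exact
# to rounding error.

.steer_cache <- new.env(parent = emptyenv())

# radial highpass window with transition [rc/2, rc] (raised cosine in log2 r)
radial_hi <- function(r, rc) {
  out <- numeric(length(r))
  out[r >= rc] <- 1
  tr <- r > rc / 2 & r < rc
  out[tr] <- cos(pi / 2 * log2(rc / r[tr]))
  out
}

radial_lo <- function(r, rc) sqrt(pmax(0, 1 - radial_hi(r, rc)^2))

# fft-order frequency vector (radians per pixel) for dimension n
fft_freqs <- function(n) {
  k <- seq_len(n) - 1L
  w <- 2 * pi * k / n
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

# indices of the centered crop of size m (even) on an fft-ordered axis of n
crop_idx <- function(n, m) c(seq_len(m / 2), seq(n - m / 2 + 1L, n))

steerable_filters <- function(h, w, scales, orientations) {
  key <- sprintf("F%d_%d_%d_%d", h, w, scales, orientations)
  if (!is.null(.steer_cache[[key]])) return(.steer_cache[[key]])
  K <- orientations
  wy <- fft_freqs(h); wx <- fft_freqs(w)
  R <- sqrt(outer(wy^2, wx^2, "+"))
  TH <- atan2(matrix(wy, h, w), matrix(wx, h, w, byrow = TRUE))
  H0 <- radial_hi(R, pi)
  # angular windows; sum over k of A_k(th)^2 + A_k(th+pi)^2 == 1 exactly
  norm_const <- K * choose(2 * K - 2, K - 1) / 4^(K - 1)
  angles <- pi * (seq_len(K) - 1) / K
  A <- lapply(angles, function(th0) {
    d <- TH - th0
    co <- cos(d)
    m <- ifelse(co > 0, co^(K - 1), 0)
    m / sqrt(norm_const)
  })
  masks <- vector("list", scales)
  dims <- vector("list", scales)
  omega_s <- numeric(scales)
  Lcum <- radial_lo(R, pi)
  dim(H0) <- dim(Lcum) <- c(h, w)
  for (s in seq_len(scales)) {
    rc <- pi / 2^s
    rad <- radial_hi(R, rc) * Lcum
    dim(rad) <- c(h, w)
    omega_s[s] <- sum(R * rad^2) / sum(rad^2)
    masks[[s]] <- lapply(A, function(a) rad * a)
    ms_h <- min(h, 2L * ceiling(h / 2^s))
    ms_w <- min(w, 2L * ceiling(w / 2^s))
    dims[[s]] <- c(ms_h, ms_w)
    Lcum <- Lcum * radial_lo(R, rc)
  }
  low_dim <- c(min(h, 2L * ceiling(h / 2^(scales + 1))),
               min(w, 2L * ceiling(w / 2^(scales + 1))))
  dim(Lcum) <- c(h, w)
  out <- list(h = h, w = w, scales = scales, orientations = K,
              H0 = H0, low = Lcum, masks = masks, band_dims = dims,
              low_dim = low_dim, omega_s = omega_s, key = key)
  .steer_cache[[key]] <- out
  out
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Crop keeps the spectrum support; the prod(m)/prod(n) factor makes the
# small-grid inverse transform a properly scaled downsampled image (a
# constant image stays at the same intensity through every scale).
crop_spectrum <- function(FF, m) {
  sc <- (m[1] * m[2]) / (nrow(FF) * ncol(FF))
  sc * FF[crop_idx(nrow(FF), m[1]), crop_idx(ncol(FF), m[2]), drop = FALSE]
}

pad_spectrum <- function(FF, n_h, n_w) {
  out <- matrix(0i, n_h, n_w)
  sc <- (n_h * n_w) / (nrow(FF) * ncol(FF))
  out[crop_idx(n_h, nrow(FF)), crop_idx(n_w, ncol(FF))] <- sc * FF
  out
}

#' Default steerable-pyramid depth for an image size
#'
#' Scales are added while the coarsest coefficient grid keeps at least 4
#' pixels per side. Deep decomposition matters because the lowpass residual
#' is never amplified: structure left in the residual is structure whose
#' motion cannot be magnified, so the pyramid is made as deep as the image
#' allows (deeper decomposition also means less noise in the output).
#'
#' @param h,w Image dimensions in pixels.
#' @return Integer number of scales.
#' @export
default_steerable_scales <- function(h, w)
  max(1L, floor(log2(min(h, w) / 4)))

#' Build a complex steerable pyramid
#'
#' Frequency-domain construction: the 2-D DFT of the image is split by an
#' outer radial high/low-pass ring, then each scale applies K oriented
#' bandpass windows (`cos^(K-1)` angular profile on the positive-frequency
#' half-plane) to yield complex analytic coefficients, recursively lowpassing
#' and decimating by 2. Presets of 4 (octave) or 8 (half-octave) orientations
#' match the amplification bounds in [pbvm_alpha_bound()]; other counts >= 2
#' are accepted.
#'
#' @param image Numeric matrix (one channel).
#' @param scales Number of scales; default via [default_steerable_scales()].
#' @param orientations Number of orientation bands per scale.
#' @return A `steerable_decomposition`: `coeffs[[s]][[k]]` complex matrices,
#'   real `highpass` and `lowpass` residuals, and `omega_s`, the
#'   representative radial frequency (rad/px) of each scale's filter.
#' @export
build_steerable <- function(image, scales = NULL, orientations = 4L) {
  image <- as.matrix(image)
  h <- nrow(image); w <- ncol(image)
  if (is.null(scales)) scales <- default_steerable_scales(h, w)
  if (orientations < 2L) stop("orientations must be >= 2")
  if (min(h, w) / 2^scales < 4L)
    stop(sprintf("image %d x %d too small for %d scales", h, w, scales))
  flt <- steerable_filters(h, w, scales, orientations)
  FF <- fft2(image)
  coeffs <- vector("list", scales)
  for (s in seq_len(scales)) {
    coeffs[[s]] <- lapply(flt$masks[[s]], function(m)
      ifft2(crop_spectrum(FF * m, flt$band_dims[[s]])))
  }
  high <- Re(ifft2(FF * flt$H0))
  low <- Re(ifft2(crop_spectrum(FF * flt$low, flt$low_dim)))
  structure(list(coeffs = coeffs, highpass = high, lowpass = low,
                 scales = scales, orientations = as.integer(orientations),
                 dim = c(h, w), omega_s = flt$omega_s),
            class = "steerable_decomposition")
}

#' Reconstruct an image from a steerable decomposition
#'
#' Inverse of [build_steerable()]: each band's spectrum is re-expanded and
#' multiplied by its (conjugate) filter, the Hermitian-symmetric part is
#' restored, and the residuals are added back — all as component-wise
#' multiplications in the Fourier domain. With unmodified coefficients the
#' round trip is exact to rounding error; the high-pass residue is required
#' for a faithful image.
#'
#' @param dec A `steerable_decomposition`.
#' @return Numeric matrix.
#' @export
reconstruct_steerable <- function(dec) {
  stopifnot(inherits(dec, "steerable_decomposition"))
  h <- dec$dim[1]; w <- dec$dim[2]
  flt <- steerable_filters(h, w, dec$scales, dec$orientations)
  acc <- matrix(0i, h, w)
  for (s in seq_len(dec$scales)) {
    for (k in seq_len(dec$orientations)) {
      co <- dec$coeffs[[s]][[k]]
      if (!all(dim(co) == flt$band_dims[[s]]))
        stop("coefficient array shape does not match the filter set")
      acc <- acc + pad_spectrum(fft2(co), h, w) * flt$masks[[s]][[k]]
    }
  }
  # restore the Hermitian-symmetric half-plane
  ridx <- c(1L, rev(seq_len(h)[-1])); cidx <- c(1L, rev(seq_len(w)[-1]))
  acc <- acc + Conj(acc[ridx, cidx])
  acc <- acc + fft2(dec$highpass) * flt$H0 +
    pad_spectrum(fft2(dec$lowpass), h, w) * flt$low
  Re(stats::fft(acc, inverse = TRUE)) / (h * w)
}

#' Amplitude and phase of complex coefficients
#'
#' Element-wise modulus and argument. The argument lies in (-pi, pi]; a zero
#' coefficient has amplitude 0 and, by convention, phase 0.
#'
#' @param coeff Complex array.
#' @return List with `amplitude` and `phase` arrays of the same shape.
#' @examples
#' amplitude_phase(matrix(c(1i, 0, -1, 1 + 1i), 2, 2))
#' @export
amplitude_phase <- function(coeff) {
  list(amplitude = Mod(coeff), phase = Arg(coeff))
}

#' @export
print.steerable_decomposition <- function(x, ...) {
  cat(sprintf("<steerable_decomposition> %d scale(s) x %d orientation(s), %d x %d px\n",
              x$scales, x$orientations, x$dim[1], x$dim[2]))
  for (s in seq_len(x$scales))
    cat(sprintf("  scale %d: %d x %d coefficients, omega = %.3f rad/px\n",
                s, nrow(x$coeffs[[s]][[1]]), ncol(x$coeffs[[s]][[1]]),
                x$omega_s[s]))
  cat(sprintf("  residuals: highpass %d x %d, lowpass %d x %d\n",
              nrow(x$highpass), ncol(x$highpass),
              nrow(x$lowpass), ncol(x$lowpass)))
  invisible(x)
}

#' Write a contact sheet of pyramid bands as PNGs
#'
#' Debug aid: writes each oriented band's amplitude (normalized to \[0,1\])
#' plus the two residuals as PNG files for visual inspection.
#'
#' @param dec A `steerable_decomposition`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
dump_decomposition_png <- function(dec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  norm01 <- function(m) {
    rng <- range(m)
    if (diff(rng) == 0) return(m * 0)
    (m - rng[1]) / diff(rng)
  }
  for (s in seq_len(dec$scales))
    for (k in seq_len(dec$orientations))
      png::writePNG(norm01(Mod(dec$coeffs[[s]][[k]])),
                    file.path(path, sprintf("scale%d_orient%d.png", s, k)))
  png::writePNG(norm01(dec$highpass), file.path(path, "highpass.png"))
  png::writePNG(norm01(dec$lowpass), file.path(path, "lowpass.png"))
  invisible(path)
}
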