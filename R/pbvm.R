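# Phase-based video magnification.
#
# Every frame is decomposed with the complex steerable pyramid; the local
# phase of each coefficient is compared against frame 0, the phase-difference
# series are temporally bandpass filtered (removing the temporal DC), scaled
# by alpha, and the original coefficients are rotated by e^{i alpha B}.
# Amplitudes are never touched, which is why phase amplification adds far
# less noise than intensity amplification: noise lives mostly in amplitudes.

#' Configuration for phase-based magnification
#'
#' @param alpha Magnification factor (>= 0).
#' @param f_l,f_h Temporal passband in Hz.
#' @param scales Steerable pyramid depth; `NULL` picks
#'   [default_steerable_scales()].
#' @param orientations 4 (octave preset) or 8 (half-octave preset).
#' @param bound_mode `"off"` (default), `"octave"` or `"half_octave"`: when
#'   not off, alpha is capped per scale at
#'   [pbvm_alpha_bound()]`(omega_s, delta_assumed, mode)`.
#' @param delta_assumed Assumed motion amplitude in px for the bound.
#' @param order Temporal Butterworth order.
#' @return A `pbvm_config` list.
#' @export
pbvm_config <- function(alpha, f_l = 0.2, f_h = 0.3, scales = NULL,
                        orientations = 4L,
                        bound_mode = c("off", "octave", "half_octave"),
                        delta_assumed = 0.1, order = 1L) {
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be finite and >= 0")
  bound_mode <- match.arg(bound_mode)
  orientations <- as.integer(orientations)
  if (bound_mode == "octave" && orientations != 4L)
    stop("octave bound mode requires 4 orientations")
  if (bound_mode == "half_octave" && orientations != 8L)
    stop("half-octave bound mode requires 8 orientations")
  structure(list(alpha = alpha, f_l = f_l, f_h = f_h, scales = scales,
                 orientations = orientations, bound_mode = bound_mode,
                 delta_assumed = delta_assumed, order = as.integer(order)),
            class = "pbvm_config")
}

#' Upper amplification limit for phase-based magnification
#'
#' The admissible phase amplification scales inversely with the band's
#' spatial frequency: alpha * delta < c / omega, with c = pi/2 (a quarter
#' wavelength) for the octave-bandwidth (4-orientation) pyramid and twice
#' that for the half-octave (8-orientation) pyramid, whose narrower bands
#' tolerate exactly double the phase shift. Low spatial frequencies can
#' therefore be magnified more than high ones.
#'
#' @param omega Band spatial frequency in rad/px (> 0).
#' @param delta Motion amplitude in px (>= 0); 0 means unbounded.
#' @param mode `"octave"` or `"half_octave"`.
#' @return Maximum alpha (possibly `Inf`).
#' @export
pbvm_alpha_bound <- function(omega, delta, mode = c("octave", "half_octave")) {
  mode <- match.arg(mode)
  if (any(omega <= 0)) stop("omega must be > 0")
  if (any(delta < 0)) stop("delta must be >= 0")
  cc <- if (mode == "half_octave") pi else pi / 2
  n <- max(length(omega), length(delta))
  om <- rep_len(omega, n)
  d <- rep_len(delta, n)
  ifelse(d == 0, Inf, cc / (om * d))
}

#' Wrap-safe phase differences between two decompositions
#'
#' Per coefficient, `delta = Arg(coeff_t * Conj(coeff_ref))`, which is exact
#' modulo 2*pi by construction and never subtracts raw angle arrays (avoiding
#' spurious +-2*pi jumps near the branch cut).
#'
#' @param dec_t,dec_ref `steerable_decomposition`s with identical structure.
#' @return A `phase_delta_stack`: list of lists of real matrices in
#'   (-pi, pi], indexed like `coeffs`.
#' @export
phase_differences <- function(dec_t, dec_ref) {
  stopifnot(inherits(dec_t, "steerable_decomposition"),
            inherits(dec_ref, "steerable_decomposition"))
  if (dec_t$scales != dec_ref$scales ||
      dec_t$orientations != dec_ref$orientations ||
      !all(dec_t$dim == dec_ref$dim))
    stop("decomposition structures do not match")
  deltas <- lapply(seq_len(dec_t$scales), function(s)
    lapply(seq_len(dec_t$orientations), function(k)
      Arg(dec_t$coeffs[[s]][[k]] * Conj(dec_ref$coeffs[[s]][[k]]))))
  structure(list(deltas = deltas, reference = 0L), class = "phase_delta_stack")
}

#' Magnify motion by phase-based magnification
#'
#' Per channel: steerable-decompose every frame; compute wrap-safe phase
#' differences against frame 0; temporally bandpass those difference series
#' (removing any temporal DC component); multiply the filtered phases by
#' alpha and rotate each coefficient by `exp(1i * alpha * B)`; reconstruct.
#' The high- and low-pass residuals pass through unmodified (phase is
#' meaningless for the real residuals), and coefficient amplitudes are never
#' altered. Assumes a mostly static scene so that frame 0 is a valid phase
#' reference.
#'
#' @param video A [video_tensor()].
#' @param config A [pbvm_config()].
#' @return Magnified [video_tensor()].
#' @export
magnify_phase <- function(video, config) {
  stopifnot(inherits(video, "video_tensor"), inherits(config, "pbvm_config"))
  validate_nyquist(config$f_l, config$f_h, video$fps)
  d <- dim(video$frames)
  h <- d[1]; w <- d[2]; nc <- d[3]; T_ <- d[4]
  scales <- if (is.null(config$scales)) default_steerable_scales(h, w)
    else config$scales
  K <- config$orientations
  spec <- design_bandpass(config$f_l, config$f_h, video$fps, config$order)
  out <- array(0, d)
  for (ch in seq_len(nc)) {
    dec0 <- build_steerable(video$frames[, , ch, 1], scales, K)
    alphas <- rep(config$alpha, scales)
    if (config$bound_mode != "off")
      alphas <- pmin(alphas, pbvm_alpha_bound(dec0$omega_s,
                                              config$delta_assumed,
                                              config$bound_mode))
    band_dims <- lapply(dec0$coeffs, function(sc) dim(sc[[1]]))
    # coefficient stacks, T x npix per (scale, orientation)
    co <- lapply(seq_len(scales), function(s)
      lapply(seq_len(K), function(k)
        matrix(0i, T_, prod(band_dims[[s]]))))
    hi <- matrix(0, T_, h * w)
    lo <- matrix(0, T_, length(dec0$lowpass))
    lo_dim <- dim(dec0$lowpass)
    for (t in seq_len(T_)) {
      dec <- if (t == 1L) dec0 else
        build_steerable(video$frames[, , ch, t], scales, K)
      for (s in seq_len(scales))
        for (k in seq_len(K))
          co[[s]][[k]][t, ] <- dec$coeffs[[s]][[k]]
      hi[t, ] <- dec$highpass
      lo[t, ] <- dec$lowpass
    }
    for (s in seq_len(scales)) {
      for (k in seq_len(K)) {
        ref <- co[[s]][[k]][1, ]
        delta <- Arg(co[[s]][[k]] *
                       matrix(Conj(ref), T_, length(ref), byrow = TRUE))
        bfilt <- filtfilt_mat(spec, delta)
        co[[s]][[k]] <- co[[s]][[k]] * exp(1i * alphas[s] * bfilt)
      }
    }
    dec <- dec0
    for (t in seq_len(T_)) {
      for (s in seq_len(scales))
        for (k in seq_len(K))
          dec$coeffs[[s]][[k]] <- matrix(co[[s]][[k]][t, ],
                                         band_dims[[s]][1], band_dims[[s]][2])
      dec$highpass <- matrix(hi[t, ], h, w)
      dec$lowpass <- matrix(lo[t, ], lo_dim[1], lo_dim[2])
      out[, , ch, t] <- reconstruct_steerable(dec)
    }
  }
  video_tensor(out, video$fps, video$colorspace)
}
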