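# Intensity-based Eulerian linear video magnification.
#
# Per channel: a Laplacian pyramid per frame, a temporal bandpass of every
# band/pixel series, amplification of the filtered signal by a per-band
# factor alpha_k, and collapse. To first order this realizes
# I_hat(x,t) = f(x + (1+alpha) delta(t)) for in-band translations delta(t).

#' Upper amplification limit for a spatial band
#'
#' The first-order Taylor synthesis underlying intensity magnification only
#' holds while the magnified displacement stays well below the band's spatial
#' wavelength: (1 + alpha) * delta <= lambda / 8. This returns the largest
#' admissible alpha, `lambda / (8 * delta) - 1` (clamped at 0), or `Inf` when
#' delta = 0 (no motion, no constraint).
#'
#' @param lambda_k Representative spatial wavelength of the band in px (> 0).
#' @param delta Assumed scene motion amplitude in px (>= 0).
#' @return Maximum alpha (possibly `Inf`).
#' @examples
#' alpha_bound(8, 1)    # 0
#' alpha_bound(800, 1)  # 99
#' @export
alpha_bound <- function(lambda_k, delta) {
  if (any(lambda_k <= 0)) stop("lambda_k must be > 0")
  if (any(delta < 0)) stop("delta must be >= 0")
  n <- max(length(lambda_k), length(delta))
  lam <- rep_len(lambda_k, n)
  d <- rep_len(delta, n)
  ifelse(d == 0, Inf, pmax(0, lam / (8 * d) - 1))
}

#' Per-band applied amplification with linear attenuation
#'
#' Bands whose representative wavelength is at least the cutoff `lambda_c`
#' receive the full alpha; finer bands are attenuated linearly,
#' `alpha * lambda_k / lambda_c`, ramping to zero — the attenuation the
#' method prescribes for spatial frequencies beyond the trustworthy range.
#' `lambda_c = 0` disables the ramp.
#'
#' @param alpha Requested amplification factor.
#' @param lambda_k Band wavelength(s) in px.
#' @param lambda_c Cutoff wavelength in px.
#' @return Applied alpha_k, same length as `lambda_k`.
#' @export
band_alpha <- function(alpha, lambda_k, lambda_c) {
  if (any(lambda_k <= 0)) stop("lambda_k must be > 0")
  if (lambda_c <= 0) return(rep(alpha, length(lambda_k)))
  ifelse(lambda_k >= lambda_c, alpha, alpha * lambda_k / lambda_c)
}

#' Configuration for intensity-based magnification
#'
#' @param alpha Magnification factor (>= 0).
#' @param f_l,f_h Temporal passband in Hz.
#' @param levels Pyramid depth; `NULL` picks [default_pyramid_levels()].
#' @param lambda_c Attenuation cutoff wavelength in px for [band_alpha()];
#'   0 (default) applies the full alpha to every band and leaves safety to
#'   the Eq-style bound below.
#' @param delta_assumed Assumed scene motion amplitude in px used by the
#'   per-band bound; 0.1 px is the order of magnitude of breathing-induced
#'   image motion at a few metres.
#' @param enforce_bound Cap each band's alpha_k at
#'   [alpha_bound()]`(lambda_k, delta_assumed)` (default TRUE). Disable to
#'   study the raw linear amplifier.
#' @param order Temporal Butterworth order.
#' @param exact_eq1_mode Use the literal first-order synthesis
#'   `I(x, 0) + (1 + alpha_k) * B(x, t)` instead of the numerically stabler
#'   default `I(x, t) + alpha_k * B(x, t)` (equivalent to first order).
#' @return An `elvm_config` list.
#' @export
elvm_config <- function(alpha, f_l = 0.2, f_h = 0.3, levels = NULL,
                        lambda_c = 0, delta_assumed = 0.1,
                        enforce_bound = TRUE, order = 1L,
                        exact_eq1_mode = FALSE) {
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be finite and >= 0")
  if (delta_assumed < 0) stop("delta_assumed must be >= 0")
  structure(list(alpha = alpha, f_l = f_l, f_h = f_h, levels = levels,
                 lambda_c = lambda_c, delta_assumed = delta_assumed,
                 enforce_bound = isTRUE(enforce_bound),
                 order = as.integer(order),
                 exact_eq1_mode = isTRUE(exact_eq1_mode)),
            class = "elvm_config")
}

# Applied per-element alphas (bands then residual) for a pyramid layout.
elvm_band_alphas <- function(config, lambdas) {
  a <- band_alpha(config$alpha, lambdas, config$lambda_c)
  if (config$enforce_bound)
    a <- pmin(a, alpha_bound(lambdas, config$delta_assumed))
  a
}

#' Magnify motion by intensity-based Eulerian linear magnification
#'
#' For every channel, builds a Laplacian pyramid of each frame, temporally
#' bandpass-filters each band's pixel series, scales the filtered signal by
#' the per-band alpha_k and adds it back, then collapses. The lowpass
#' residual is treated as the coarsest band (with its own wavelength), so
#' smooth large-scale motion is amplified too. For a scene translating by an
#' in-band delta(t), the output motion is approximately (1 + alpha) delta(t).
#'
#' @param video A [video_tensor()].
#' @param config An [elvm_config()].
#' @return Magnified [video_tensor()] with the same shape and fps. Values
#'   may transiently leave \[0,1\]; they are clipped only on export.
#' @export
magnify_intensity <- function(video, config) {
  stopifnot(inherits(video, "video_tensor"), inherits(config, "elvm_config"))
  validate_nyquist(config$f_l, config$f_h, video$fps)
  d <- dim(video$frames)
  h <- d[1]; w <- d[2]; nc <- d[3]; T_ <- d[4]
  levels <- if (is.null(config$levels)) default_pyramid_levels(h, w)
    else config$levels
  spec <- design_bandpass(config$f_l, config$f_h, video$fps, config$order)
  out <- array(0, d)
  for (ch in seq_len(nc)) {
    pyr0 <- build_laplacian_pyramid(video$frames[, , ch, 1], levels)
    lambdas <- c(pyr0$lambda_bands, pyr0$lambda_residual)
    alphas <- elvm_band_alphas(config, lambdas)
    nelem <- levels  # levels-1 bands + residual
    elem_dims <- c(lapply(pyr0$bands, dim), list(dim(pyr0$residual)))
    stacks <- lapply(elem_dims, function(dd) matrix(0, T_, prod(dd)))
    for (e in seq_len(nelem)) {
      stacks[[e]][1, ] <- if (e < nelem) pyr0$bands[[e]] else pyr0$residual
    }
    for (t in seq(2L, T_)) {
      p <- build_laplacian_pyramid(video$frames[, , ch, t], levels)
      for (e in seq_len(nelem))
        stacks[[e]][t, ] <- if (e < nelem) p$bands[[e]] else p$residual
    }
    for (e in seq_len(nelem)) {
      filt <- filtfilt_mat(spec, stacks[[e]])
      if (config$exact_eq1_mode) {
        base <- matrix(stacks[[e]][1, ], T_, ncol(filt), byrow = TRUE)
        stacks[[e]] <- base + (1 + alphas[e]) * filt
      } else {
        stacks[[e]] <- stacks[[e]] + alphas[e] * filt
      }
    }
    pyr <- pyr0
    for (t in seq_len(T_)) {
      for (e in seq_len(nelem)) {
        m <- matrix(stacks[[e]][t, ], elem_dims[[e]][1], elem_dims[[e]][2])
        if (e < nelem) pyr$bands[[e]] <- m else pyr$residual <- m
      }
      out[, , ch, t] <- collapse_laplacian(pyr)
    }
  }
  video_tensor(out, video$fps, video$colorspace)
}
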