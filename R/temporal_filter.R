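#' Design a temporal Butterworth bandpass filter
#'
#' Builds the digital Butterworth bandpass used to isolate the temporal
#' frequency band containing the motion of interest (for adult breathing,
#' 0.2-0.3 Hz). Butterworth filters are maximally flat in the passband and
#' monotonic overall, which avoids passband ripple being mistaken for motion
#' structure. Coefficients come from [signal::butter()]; application is
#' zero-phase (forward-backward, see [apply_bandpass()]), so the realized
#' magnitude response is the square of the single-pass response returned by
#' [bandpass_gain()].
#'
#' @param f_l,f_h Passband edges in Hz, `0 < f_l < f_h < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Filter order (per lowpass prototype); the default 1 is the
#'   classic choice for Eulerian magnification, giving gentle band edges and
#'   short transients.
#' @return A `bandpass_spec`: list with `b`, `a` coefficient vectors and the
#'   design parameters.
#' @examples
#' spec <- design_bandpass(0.2, 0.3, fs = 50)
#' bandpass_gain(spec, c(0, 0.245, 2))
#' @export
design_bandpass <- function(f_l, f_h, fs, order = 1L) {
  if (!is.finite(f_l) || f_l <= 0) stop("f_l must be > 0")
  if (!is.finite(f_h) || f_h <= f_l) stop("f_h must exceed f_l")
  if (f_h >= fs / 2)
    stop(sprintf("f_h = %g Hz must be below the Nyquist frequency %g Hz",
                 f_h, fs / 2))
  if (order < 1L) stop("order must be >= 1")
  flt <- signal::butter(order, c(f_l, f_h) / (fs / 2), type = "pass")
  structure(list(b = as.numeric(flt$b), a = as.numeric(flt$a),
                 f_l = f_l, f_h = f_h, fs = fs, order = as.integer(order),
                 kind = "butterworth"),
            class = "bandpass_spec")
}

#' Single-pass magnitude response of a bandpass filter
#'
#' Evaluates |H(f)| of the realized transfer function at the given
#' frequencies. The forward-backward application used by [apply_bandpass()]
#' realizes |H(f)|^2.
#'
#' @param spec A `bandpass_spec` from [design_bandpass()].
#' @param f Frequencies in Hz.
#' @return Numeric vector of gains.
#' @export
bandpass_gain <- function(spec, f) {
  stopifnot(inherits(spec, "bandpass_spec"))
  z <- exp(-2i * pi * f / spec$fs)
  num <- vapply(z, function(zz) sum(spec$b * zz^(seq_along(spec$b) - 1)),
                complex(1))
  den <- vapply(z, function(zz) sum(spec$a * zz^(seq_along(spec$a) - 1)),
                complex(1))
  Mod(num / den)
}

# Steady-state initial filter state for a unit-amplitude step input,
# so that forward-backward filtering does not ring at the series edges.
# Solves (I - A) zi = B for the direct-form-II-transposed state.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1L) return(numeric(0))
  # companion matrix of a, transposed
  A <- matrix(0, n - 1, n - 1)
  if (n > 2L) A[cbind(seq_len(n - 2) + 1L, seq_len(n - 2))] <- 1
  A[1, ] <- -a[-1]
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# One forward IIR pass over the columns of X (time along rows), with initial
# state zi scaled per column. Direct form II transposed, vectorized across
# columns.
lfilter_mat <- function(b, a, X, zi_scale = NULL) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  T_ <- nrow(X); P <- ncol(X)
  Y <- matrix(0, T_, P)
  z <- matrix(0, n - 1, P)
  if (!is.null(zi_scale)) {
    zi <- lfilter_zi(b, a)
    z <- zi %o% zi_scale
  }
  for (t in seq_len(T_)) {
    xt <- X[t, ]
    yt <- b[1] * xt + z[1, ]
    if (n > 2L) {
      for (k in seq_len(n - 2L))
        z[k, ] <- b[k + 1] * xt + z[k + 1, ] - a[k + 1] * yt
    }
    z[n - 1, ] <- b[n] * xt - a[n] * yt
    Y[t, ] <- yt
  }
  Y
}

# Zero-phase (forward-backward) filtering along the rows (time) of a T x P
# matrix, with odd-reflect padding of 3*max(len(a), len(b)) samples and
# steady-state initial conditions at both ends.
filtfilt_mat <- function(spec, X) {
  b <- spec$b; a <- spec$a
  T_ <- nrow(X)
  padlen <- 3L * max(length(a), length(b))
  if (T_ <= padlen)
    stop(sprintf("time series too short: need more than %d samples, got %d",
                 padlen, T_))
  front <- 2 * matrix(X[1, ], padlen, ncol(X), byrow = TRUE) -
    X[seq(padlen + 1L, 2L), , drop = FALSE]
  back <- 2 * matrix(X[T_, ], padlen, ncol(X), byrow = TRUE) -
    X[seq(T_ - 1L, T_ - padlen), , drop = FALSE]
  Xp <- rbind(front, X, back)
  Y <- lfilter_mat(b, a, Xp, zi_scale = Xp[1, ])
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  Y <- lfilter_mat(b, a, Y, zi_scale = Y[1, ])
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  Y[seq(padlen + 1L, padlen + T_), , drop = FALSE]
}

# Ideal (FFT brick-wall) zero-phase bandpass along rows of a T x P matrix.
# Cross-check oracle, not the default path.
ideal_bandpass_mat <- function(f_l, f_h, fs, X) {
  T_ <- nrow(X)
  f <- (seq_len(T_) - 1) / T_ * fs
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  keep <- f >= f_l & f <= f_h
  Xf <- stats::mvfft(X)
  Xf[!keep, ] <- 0
  Re(stats::mvfft(Xf, inverse = TRUE)) / T_
}

#' Apply a temporal bandpass filter to a time series
#'
#' Zero-phase (forward-backward) application: the filter is run forward and
#' backward in time so the output has no phase lag, which matters because a
#' lag would shift the apparent motion. Edges are stabilized by odd-reflect
#' padding plus steady-state initial conditions. The output has the same
#' length as the input and (being a bandpass) essentially zero mean.
#'
#' @param series Numeric vector.
#' @param spec A `bandpass_spec` from [design_bandpass()].
#' @param method `"butterworth"` (default, zero-phase IIR) or `"ideal"` (FFT
#'   brick-wall, provided as a cross-check oracle).
#' @return Filtered numeric vector of the same length.
#' @export
apply_bandpass <- function(series, spec, method = c("butterworth", "ideal")) {
  method <- match.arg(method)
  X <- matrix(as.numeric(series), ncol = 1)
  if (method == "ideal")
    return(drop(ideal_bandpass_mat(spec$f_l, spec$f_h, spec$fs, X)))
  drop(filtfilt_mat(spec, X))
}

#' Apply a temporal bandpass filter across a spatial stack
#'
#' Filters every spatial position of a band stack independently along time
#' with the identical filter — the uniform treatment of all pixels and all
#' pyramid levels that makes the magnification Eulerian. Complex input (e.g.
#' steerable-pyramid coefficients) is not accepted here; phase-based code
#' filters the real-valued phase-difference series.
#'
#' @param stack Numeric matrix with time along the FIRST dimension (T x
#'   n_positions), or a 3-D array H x W x T.
#' @param spec A `bandpass_spec`.
#' @param method See [apply_bandpass()].
#' @return Filtered object of the same shape.
#' @export
apply_bandpass_stack <- function(stack, spec,
                                 method = c("butterworth", "ideal")) {
  method <- match.arg(method)
  if (is.complex(stack)) stop("complex input: filter the phase series instead")
  if (is.array(stack) && length(dim(stack)) == 3L) {
    d <- dim(stack)
    X <- t(matrix(stack, d[1] * d[2], d[3]))  # T x npix
    Y <- if (method == "ideal")
      ideal_bandpass_mat(spec$f_l, spec$f_h, spec$fs, X) else
        filtfilt_mat(spec, X)
    return(array(t(Y), d))
  }
  if (!is.matrix(stack)) stop("stack must be a T x P matrix or H x W x T array")
  if (method == "ideal")
    ideal_bandpass_mat(spec$f_l, spec$f_h, spec$fs, stack) else
      filtfilt_mat(spec, stack)
}
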