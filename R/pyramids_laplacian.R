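# Gaussian / Laplacian pyramids.
#
# The blur kernel is the 5-tap binomial [1,4,6,4,1]/16 (Burt-Adelson), applied
# separably with whole-sample reflect boundary handling. All resampling is
# expressed as banded operator matrices so that one level transition is a pair
# of small matrix products; this keeps odd sizes exact (downsampled length is
# ceiling(n/2), upsampling targets the recorded partner length).

.pyr_cache <- new.env(parent = emptyenv())

binomial5 <- c(1, 4, 6, 4, 1) / 16

# n x n blur operator with reflect boundary (whole-sample: index 0 -> 2).
blur_op <- function(n) {
  key <- paste0("B", n)
  if (!is.null(.pyr_cache[[key]])) return(.pyr_cache[[key]])
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in -2:2) {
      j <- i + k
      if (j < 1L) j <- 2L - j
      if (j > n) j <- 2L * n - j
      B[i, j] <- B[i, j] + binomial5[k + 3L]
    }
  }
  .pyr_cache[[key]] <- B
  B
}

# ceiling(n/2) x n blur-and-decimate operator (keep odd indices 1,3,5,...).
reduce_op <- function(n) {
  key <- paste0("D", n)
  if (!is.null(.pyr_cache[[key]])) return(.pyr_cache[[key]])
  D <- blur_op(n)[seq(1L, n, by = 2L), , drop = FALSE]
  .pyr_cache[[key]] <- D
  D
}

# n x ceiling(n/2) zero-stuff-and-blur upsampling operator (kernel doubled so
# a constant image upsamples to the same constant).
expand_op <- function(n) {
  key <- paste0("U", n)
  if (!is.null(.pyr_cache[[key]])) return(.pyr_cache[[key]])
  m <- ceiling(n / 2)
  Z <- matrix(0, n, m)
  Z[cbind(seq(1L, n, by = 2L), seq_len(m))] <- 1
  U <- (2 * blur_op(n)) %*% Z
  .pyr_cache[[key]] <- U
  U
}

blur_image <- function(img) blur_op(nrow(img)) %*% img %*% t(blur_op(ncol(img)))

reduce_image <- function(img)
  reduce_op(nrow(img)) %*% img %*% t(reduce_op(ncol(img)))

expand_image <- function(img, target_dim)
  expand_op(target_dim[1]) %*% img %*% t(expand_op(target_dim[2]))

check_pyr_levels <- function(img, levels) {
  if (levels < 1L) stop("levels must be >= 1")
  if (min(dim(img)) < 2^(levels - 1))
    stop(sprintf("image %d x %d too small for %d levels",
                 nrow(img), ncol(img), levels))
}

#' Default pyramid depth for an image size
#'
#' Levels are added while the coarsest level keeps a minimum dimension of at
#' least `min_size` pixels (default 12), deep enough that breathing-scale
#' spatial structure reaches a band rather than being buried in the residual.
#'
#' @param h,w Image dimensions in pixels.
#' @param min_size Minimum dimension of the coarsest level.
#' @return Integer number of levels (>= 2 when the image allows it).
#' @export
default_pyramid_levels <- function(h, w, min_size = 12) {
  max(2L, floor(log2(min(h, w) / min_size)) + 1L)
}

#' Build a Gaussian pyramid
#'
#' Level 0 is the input; each subsequent level is the previous one blurred
#' with a 5-tap binomial kernel (reflect boundary) and decimated by 2.
#'
#' @param image Numeric matrix.
#' @param levels Number of levels (level 0 counts).
#' @return List of matrices, finest first.
#' @export
build_gaussian_pyramid <- function(image, levels) {
  image <- as.matrix(image)
  check_pyr_levels(image, levels)
  g <- vector("list", levels)
  g[[1]] <- image
  for (k in seq_len(levels - 1L)) g[[k + 1]] <- reduce_image(g[[k]])
  g
}

#' Build a Laplacian pyramid
#'
#' Band k is the difference between Gaussian level k and the upsampled level
#' k+1, so the pyramid is a sequence of band-pass, down-sampled images; the
#' coarsest Gaussian level is kept as the lowpass residual, which makes the
#' decomposition exactly invertible ([collapse_laplacian()]).
#'
#' Each element carries a representative spatial wavelength lambda (px): the
#' residual — the lowest-frequency element — takes the frame diagonal / 3, and
#' lambda halves per finer band, following the convention of the original
#' Eulerian-magnification implementation. These wavelengths drive the
#' amplification bound ([alpha_bound()]) and attenuation ramp ([band_alpha()]).
#'
#' @param image Numeric matrix.
#' @param levels Total number of pyramid elements: `levels - 1` bandpass bands
#'   plus the lowpass residual.
#' @return A `laplacian_pyramid`: list with `bands` (list of matrices, finest
#'   first), `residual`, `lambda_bands`, `lambda_residual`.
#' @export
build_laplacian_pyramid <- function(image, levels) {
  g <- build_gaussian_pyramid(image, levels)
  nb <- levels - 1L
  bands <- vector("list", nb)
  for (k in seq_len(nb))
    bands[[k]] <- g[[k]] - expand_image(g[[k + 1]], dim(g[[k]]))
  lam_res <- sqrt(nrow(image)^2 + ncol(image)^2) / 3
  lam_bands <- if (nb > 0) lam_res / 2^((levels - 1L) - (seq_len(nb) - 1L))
    else numeric(0)
  structure(list(bands = bands, residual = g[[levels]],
                 lambda_bands = lam_bands, lambda_residual = lam_res),
            class = "laplacian_pyramid")
}

#' Collapse a Laplacian pyramid back to an image
#'
#' Exact inverse of [build_laplacian_pyramid()]: the residual is upsampled and
#' summed with the bands from coarse to fine.
#'
#' @param pyr A `laplacian_pyramid`.
#' @return Numeric matrix.
#' @export
collapse_laplacian <- function(pyr) {
  stopifnot(inherits(pyr, "laplacian_pyramid"))
  img <- pyr$residual
  for (k in rev(seq_along(pyr$bands))) {
    target <- dim(pyr$bands[[k]])
    if (!all(dim(img) * 2L >= target))
      stop("pyramid level shapes are inconsistent")
    img <- pyr$bands[[k]] + expand_image(img, target)
  }
  img
}

#' @export
print.laplacian_pyramid <- function(x, ...) {
  cat(sprintf("<laplacian_pyramid> %d band(s) + residual\n", length(x$bands)))
  for (k in seq_along(x$bands))
    cat(sprintf("  band %d: %d x %d, lambda = %.1f px\n", k - 1L,
                nrow(x$bands[[k]]), ncol(x$bands[[k]]), x$lambda_bands[k]))
  cat(sprintf("  residual: %d x %d, lambda = %.1f px\n",
              nrow(x$residual), ncol(x$residual), x$lambda_residual))
  invisible(x)
}
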