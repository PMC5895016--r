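ls_amp <- function(v, f, fs) {
  tt <- (seq_along(v) - 1) / fs
  X <- cbind(1, cos(2 * pi * f * tt), sin(2 * pi * f * tt))
  cf <- stats::lm.fit(X, v)$coefficients
  sqrt(cf[2]^2 + cf[3]^2)
}

test_that("bandpass design kills DC, passes the band centre, guards Nyquist", {
  spec <- design_bandpass(0.2, 0.3, fs = 50)
  expect_lt(bandpass_gain(spec, 0), 1e-3)
  g_mid <- bandpass_gain(spec, 0.245)
  expect_gte(g_mid, 0.95)
  expect_lte(g_mid, 1.0)
  expect_error(design_bandpass(0.2, 0.3, fs = 0.5), "Nyquist")
  expect_error(design_bandpass(0, 0.3, fs = 50), "> 0")
  expect_error(design_bandpass(0.3, 0.2, fs = 50), "exceed")
})

test_that("in-band sinusoids pass near unity, out-of-band ones are rejected", {
  fs <- 50
  spec <- design_bandpass(0.2, 0.3, fs)
  tt <- seq(0, 60, by = 1 / fs)
  for (method in c("butterworth", "ideal")) {
    y_in <- apply_bandpass(sin(2 * pi * 0.25 * tt), spec, method = method)
    expect_gte(ls_amp(y_in, 0.25, fs), 0.9)
    expect_lte(ls_amp(y_in, 0.25, fs), 1.05)
    y_out <- apply_bandpass(sin(2 * pi * 2 * tt), spec, method = method)
    expect_lt(ls_amp(y_out, 2, fs), 0.05)
  }
})

test_that("constant input is removed and short series rejected", {
  spec <- design_bandpass(0.2, 0.3, 10)
  expect_lt(max(abs(apply_bandpass(rep(3.2, 200), spec))), 1e-6)
  expect_error(apply_bandpass(rep(1, 5), spec), "too short")
})

test_that("filtering is linear and time-invariant", {
  spec <- design_bandpass(0.5, 1.5, 10)
  set.seed(20)
  x1 <- rnorm(300); x2 <- rnorm(300)
  y12 <- apply_bandpass(2 * x1 - 3 * x2, spec)
  expect_equal(y12, 2 * apply_bandpass(x1, spec) - 3 * apply_bandpass(x2, spec),
               tolerance = 1e-10)
  # time invariance, checked away from the edges
  sh <- 25L
  xs <- c(rep(0, sh), x1[1:(300 - sh)])
  y1 <- apply_bandpass(c(x1, rep(0, 100)), spec)
  ys <- apply_bandpass(c(xs, rep(0, 100 - sh), rep(0, sh)), spec)
  mid <- 100:250
  expect_equal(ys[mid + sh], y1[mid], tolerance = 1e-4)
})

test_that("zero-phase filtering leaves the in-band phase untouched", {
  fs <- 10
  spec <- design_bandpass(0.2, 0.3, fs)
  tt <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * 0.25 * tt)
  y <- apply_bandpass(x, spec)
  mid <- 150:500  # steady state, away from the warm-up
  fit <- function(v) {
    cf <- stats::lm.fit(cbind(cos(2 * pi * 0.25 * tt[mid]),
                              sin(2 * pi * 0.25 * tt[mid])), v[mid])$coefficients
    atan2(cf[1], cf[2])
  }
  lag_s <- (fit(y) - fit(x)) / (2 * pi * 0.25)
  expect_lt(abs(lag_s), 1 / fs)  # aligned within one sample
  # DC removal: the ideal path is exact, the IIR path is limited by its edge
  # transients
  expect_lt(abs(mean(apply_bandpass(x, spec, method = "ideal"))), 1e-12)
  expect_lt(abs(mean(y)), 0.01 * stats::sd(x))
})

test_that("stack filtering equals looping the 1-D filter over every pixel", {
  set.seed(21)
  spec <- design_bandpass(0.2, 0.3, 10)
  X <- matrix(rnorm(200 * 12), 200, 12)
  Y <- apply_bandpass_stack(X, spec)
  for (j in seq_len(ncol(X)))
    expect_equal(Y[, j], apply_bandpass(X[, j], spec), tolerance = 1e-12)
  # spatial independence: one oscillating pixel leaves the rest silent
  tt <- (0:199) / 10
  Z <- matrix(1, 200, 12)
  Z[, 5] <- 1 + sin(2 * pi * 0.25 * tt)
  F <- apply_bandpass_stack(Z, spec)
  expect_gt(max(abs(F[, 5])), 0.5)
  expect_lt(max(abs(F[, -5])), 1e-6)
  # permuting positions before filtering = permuting after
  perm <- sample(12)
  expect_equal(apply_bandpass_stack(Z[, perm], spec), F[, perm],
               tolerance = 1e-12)
  # 3-D array form round-trips the layout
  A <- array(rnorm(6 * 4 * 100), c(6, 4, 100))
  FA <- apply_bandpass_stack(A, spec)
  expect_equal(dim(FA), dim(A))
  expect_equal(FA[3, 2, ], apply_bandpass(A[3, 2, ], spec), tolerance = 1e-12)
  expect_error(apply_bandpass_stack(matrix(1i, 50, 2), spec), "complex")
})

test_that("the Butterworth path agrees with the ideal-filter oracle in band", {
  fs <- 10
  spec <- design_bandpass(0.2, 0.3, fs)
  tt <- seq(0, 120, by = 1 / fs)
  x <- 0.7 * sin(2 * pi * 0.25 * tt) + 0.4 * sin(2 * pi * 1.7 * tt) + 0.2
  yb <- apply_bandpass(x, spec)
  yi <- apply_bandpass(x, spec, method = "ideal")
  expect_equal(ls_amp(yb, 0.25, fs), ls_amp(yi, 0.25, fs), tolerance = 0.06)
  expect_lt(ls_amp(yb, 1.7, fs), 0.02)
  expect_lt(ls_amp(yi, 1.7, fs), 0.02)
})
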