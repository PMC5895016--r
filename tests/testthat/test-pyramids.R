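# brute-force separable blur + decimation, used as the independent oracle
# for one Gaussian pyramid step
brute_blur_decimate <- function(img) {
  k <- c(1, 4, 6, 4, 1) / 16
  h <- nrow(img); w <- ncol(img)
  refl <- function(j, n) ifelse(j < 1, 2 - j, ifelse(j > n, 2 * n - j, j))
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (a in -2:2) for (b in -2:2)
      acc <- acc + k[a + 3] * k[b + 3] * img[refl(i + a, h), refl(j + b, w)]
    out[i, j] <- acc
  }
  out[seq(1, h, 2), seq(1, w, 2), drop = FALSE]
}

test_that("Gaussian pyramid levels match shape and a direct convolution oracle", {
  img <- matrix(0.5, 64, 48)
  g <- build_gaussian_pyramid(img, 3)
  expect_equal(lapply(g, dim), list(c(64L, 48L), c(32L, 24L), c(16L, 12L)))
  expect_true(all(vapply(g, function(m) max(abs(m - 0.5)), 1) < 1e-14))
  imp <- matrix(0, 16, 16); imp[8, 8] <- 1
  g2 <- build_gaussian_pyramid(imp, 2)
  expect_equal(g2[[2]], brute_blur_decimate(imp), tolerance = 1e-14)
  set.seed(3)
  rnd <- matrix(runif(31 * 17), 31, 17)  # odd sizes: ceiling(n/2)
  g3 <- build_gaussian_pyramid(rnd, 3)
  expect_equal(dim(g3[[2]]), c(16L, 9L))
  expect_equal(g3[[2]], brute_blur_decimate(rnd), tolerance = 1e-14)
  expect_error(build_gaussian_pyramid(matrix(0, 4, 4), 8), "too small")
})

test_that("Laplacian pyramid is an exact band-difference decomposition", {
  const <- matrix(0.7, 32, 32)
  p <- build_laplacian_pyramid(const, 3)
  expect_true(all(vapply(p$bands, function(b) max(abs(b)), 1) < 1e-12))
  expect_equal(max(abs(p$residual - 0.7)), 0, tolerance = 1e-12)
  set.seed(4)
  img <- matrix(runif(32 * 32), 32, 32)
  p2 <- build_laplacian_pyramid(img, 2)
  g <- brute_blur_decimate(img)
  oracle_h0 <- img - vitalmag:::expand_image(g, c(32L, 32L))
  expect_equal(p2$bands[[1]], oracle_h0, tolerance = 1e-12)
  expect_equal(p2$residual, g, tolerance = 1e-12)
})

test_that("build -> collapse reproduces images within 1e-10", {
  set.seed(5)
  for (i in 1:10) {
    img <- matrix(runif(64 * 64), 64, 64)
    p <- build_laplacian_pyramid(img, 4)
    expect_lt(max(abs(collapse_laplacian(p) - img)), 1e-10)
  }
  odd <- matrix(runif(45 * 37), 45, 37)
  expect_lt(max(abs(collapse_laplacian(build_laplacian_pyramid(odd, 3)) - odd)),
            1e-10)
})

test_that("collapsing only the residual preserves the image mean", {
  # the binomial kernel preserves the mean up to boundary folding, which
  # contributes O(1/n): a 64 x 64 image keeps its mean to ~1e-4
  set.seed(6)
  img <- matrix(runif(64 * 64), 64, 64)
  p <- build_laplacian_pyramid(img, 3)
  p$bands <- lapply(p$bands, function(b) b * 0)
  low <- collapse_laplacian(p)
  expect_equal(mean(low), mean(img), tolerance = 1e-3)
  expect_lt(stats::sd(low), stats::sd(img))  # it is a lowpass approximation
})

test_that("pyramid wavelengths halve from the residual toward fine bands", {
  p <- build_laplacian_pyramid(matrix(0, 96, 96), 4)
  expect_equal(p$lambda_residual, sqrt(2) * 96 / 3)
  expect_equal(p$lambda_bands,
               p$lambda_residual / c(8, 4, 2))
  expect_lt(p$lambda_bands[1], p$lambda_bands[2])  # finest band, smallest lambda
})

test_that("steerable decomposition has the advertised structure", {
  # white circle on black, 2 scales x 6 orientations:
  # 12 oriented bands + highpass + lowpass residuals
  xy <- outer((1:64 - 32.5)^2, (1:64 - 32.5)^2, "+")
  circ <- 1 * (xy < 15^2)
  d <- build_steerable(circ, 2, 6)
  expect_length(d$coeffs, 2)
  expect_true(all(vapply(d$coeffs, length, 1L) == 6))
  expect_true(is.matrix(d$highpass) && is.matrix(d$lowpass))
  const <- matrix(0.4, 32, 32)
  dc <- build_steerable(const, 2, 4)
  maxband <- max(vapply(dc$coeffs, function(sc)
    max(vapply(sc, function(co) max(Mod(co)), 1)), 1))
  expect_lt(maxband, 1e-12)
  expect_equal(mean(dc$lowpass), 0.4, tolerance = 1e-10)
  expect_error(build_steerable(matrix(0, 8, 8), 4, 4), "too small")
})

test_that("an oriented sinusoid lands in the matching band with the analytic share", {
  # the cos^(K-1) angular windows overlap by design, so a sinusoid at a
  # window centre takes the share cos^(2K-2)(0) / sum_j cos^(2K-2)(dtheta_j)
  # of the scale's energy; the matching band always dominates
  n <- 64
  for (K in c(4L, 6L)) {
    share_pred <- local({
      th_j <- pi * (seq_len(K) - 1) / K
      w <- pmax(cos(th_j), 0)^(2 * K - 2) + pmax(cos(th_j - pi), 0)^(2 * K - 2)
      w[1] / sum(w)
    })
    for (kor in seq_len(K)) {
      th <- pi * (kor - 1) / K
      om <- pi / 2  # peak gain of scale 1's radial window, an exact DFT bin
      X <- matrix(rep(1:n, each = n), n, n)  # X[i, j] = j
      Y <- matrix(rep(1:n, n), n, n)         # Y[i, j] = i
      img <- cos(om * cos(th) * X + om * sin(th) * Y)
      d <- build_steerable(img, 2, K)
      energy <- vapply(seq_len(K), function(k)
        sum(Mod(d$coeffs[[1]][[k]])^2), 1)
      expect_equal(which.max(energy), kor)
      expect_equal(energy[kor] / sum(energy), share_pred, tolerance = 0.05)
    }
  }
})

test_that("steerable reconstruction exceeds 40 dB for standard configurations", {
  set.seed(7)
  for (cfg in list(c(2, 4), c(3, 4), c(2, 8))) {
    img <- matrix(runif(64 * 64), 64, 64)
    r <- reconstruct_steerable(build_steerable(img, cfg[1], cfg[2]))
    mse <- mean((255 * (r - img))^2)
    expect_gt(10 * log10(255^2 / mse), 40)
  }
  const <- matrix(0.3, 48, 48)
  rc <- reconstruct_steerable(build_steerable(const, 2, 4))
  expect_lt(max(abs(rc - const)), 1e-8)
})

test_that("dropping the high-pass residual degrades reconstruction", {
  set.seed(8)
  img <- matrix(runif(48 * 48), 48, 48)
  d <- build_steerable(img, 2, 4)
  full <- reconstruct_steerable(d)
  d$highpass <- d$highpass * 0
  ablated <- reconstruct_steerable(d)
  expect_gt(mean((ablated - img)^2), mean((full - img)^2))
})

test_that("both decompositions are linear maps", {
  set.seed(9)
  a <- 2.5; b <- -0.7
  I1 <- matrix(runif(32 * 32), 32, 32)
  I2 <- matrix(runif(32 * 32), 32, 32)
  pI <- build_laplacian_pyramid(a * I1 + b * I2, 3)
  p1 <- build_laplacian_pyramid(I1, 3)
  p2 <- build_laplacian_pyramid(I2, 3)
  for (k in seq_along(pI$bands))
    expect_equal(pI$bands[[k]], a * p1$bands[[k]] + b * p2$bands[[k]],
                 tolerance = 1e-8)
  sI <- build_steerable(a * I1 + b * I2, 2, 4)
  s1 <- build_steerable(I1, 2, 4)
  s2 <- build_steerable(I2, 2, 4)
  expect_equal(sI$coeffs[[2]][[3]],
               a * s1$coeffs[[2]][[3]] + b * s2$coeffs[[2]][[3]],
               tolerance = 1e-8)
})

test_that("steerable coefficient energy is bounded by the input energy", {
  set.seed(10)
  for (i in 1:5) {
    img <- matrix(runif(48 * 48), 48, 48)
    img <- img - mean(img)
    d <- build_steerable(img, 3, 4)
    energy <- sum(d$highpass^2) + sum(d$lowpass^2) +
      sum(vapply(d$coeffs, function(sc)
        sum(vapply(sc, function(co) sum(Mod(co)^2), 1)), 1))
    expect_lt(energy, 1.5 * sum(img^2))
  }
})

test_that("amplitude_phase is the polar round trip with the stated conventions", {
  ap <- amplitude_phase(1i)
  expect_equal(ap$amplitude, 1)
  expect_equal(ap$phase, pi / 2)
  ap0 <- amplitude_phase(0 + 0i)
  expect_equal(ap0$amplitude, 0)
  expect_equal(ap0$phase, 0)
  set.seed(11)
  z <- complex(real = rnorm(100), imaginary = rnorm(100))
  ap2 <- amplitude_phase(z)
  expect_true(all(ap2$phase > -pi & ap2$phase <= pi))
  expect_lt(max(Mod(ap2$amplitude * exp(1i * ap2$phase) - z)), 1e-12)
})
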