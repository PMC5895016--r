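test_that("scene generation matches its spec and is deterministic", {
  sp <- scene_spec(fps = 10, duration = 60)
  sc <- generate_breathing_video(sp)
  expect_equal(n_frames(sc$video), 600L)
  expect_equal(nrow(sc$truth), 600L)
  # sin(2 pi f t) = 0 at t = 2 s (frame 21): frame identical to the base frame
  expect_equal(sc$truth$dx[21], 0, tolerance = 1e-12)
  expect_equal(sc$video$frames[, , 1, 21], sc$video$frames[, , 1, 1],
               tolerance = 1e-12)
  # same seed => bit identical; noiseless component independent of seed
  n1 <- generate_breathing_video(scene_spec(duration = 5, noise_sigma = 0.02,
                                            seed = 5))
  n2 <- generate_breathing_video(scene_spec(duration = 5, noise_sigma = 0.02,
                                            seed = 5))
  n3 <- generate_breathing_video(scene_spec(duration = 5, noise_sigma = 0.02,
                                            seed = 6))
  expect_identical(n1$video$frames, n2$video$frames)
  expect_false(identical(n1$video$frames, n3$video$frames))
  c1 <- generate_breathing_video(scene_spec(duration = 5, seed = 5))
  c2 <- generate_breathing_video(scene_spec(duration = 5, seed = 6))
  expect_identical(c1$video$frames, c2$video$frames)
  expect_error(scene_spec(freq = 6, fps = 10), "Nyquist")
  expect_error(scene_spec(duration = 0.05, fps = 10), ">= 2 frames")
  expect_error(scene_spec(delta0 = -1), "delta0")
})

test_that("pure translation keeps per-frame pattern energy constant", {
  sc <- generate_breathing_video(scene_spec(duration = 10, delta0 = 0.5))
  bg <- sc$spec$background
  energy <- apply((sc$video$frames - bg)^2, 4, sum)
  expect_lt(diff(range(energy)) / mean(energy), 1e-3)
})

test_that("the generated motion's spectral peak sits at the spec frequency", {
  sc <- generate_breathing_video(scene_spec(duration = 30, delta0 = 0.5))
  tr <- measure_displacement(sc$video)
  br <- estimate_breath_rate(tr)
  expect_true(br$detected)
  expect_lt(abs(br$freq_hz - sc$spec$freq), 1 / 30 + 1e-9)  # within one bin
})

test_that("camera shake adds a global offset recorded in the ground truth", {
  # shake at 0.5 Hz so the 10 fps sampling grid hits the sinusoid's peaks
  sp <- scene_spec(duration = 10, delta0 = 0, shake_amp = 0.4,
                   shake_freq = 0.5)
  sc <- generate_breathing_video(sp)
  expect_equal(max(abs(sc$truth$shake)), 0.4)
  expect_equal(sc$truth$dx, sc$truth$breathing + sc$truth$shake)
  amp <- amp_central(measure_displacement(sc$video), 0.5)
  expect_equal(amp, 0.4, tolerance = 0.05)
})

test_that("multi-subject composition is exact, order-free and overlap-checked", {
  one <- scene_spec(duration = 5)
  solo <- generate_breathing_video(one)
  ms1 <- generate_multi_subject_scene(list(one))
  expect_equal(ms1$video$frames, solo$video$frames, tolerance = 1e-12)
  a <- scene_spec(width = 192, cx = 48, duration = 5, freq = 0.2)
  b <- scene_spec(width = 192, cx = 144, duration = 5, freq = 0.25)
  ab <- generate_multi_subject_scene(list(a, b))
  ba <- generate_multi_subject_scene(list(b, a))
  expect_equal(ab$video$frames, ba$video$frames, tolerance = 1e-12)
  expect_error(generate_multi_subject_scene(
    list(a, scene_spec(width = 192, cx = 52, duration = 5))), "overlap")
  expect_error(generate_multi_subject_scene(
    list(a, scene_spec(width = 96, cx = 48, duration = 5))), "share")
})

test_that("all three pattern families render and translate analytically", {
  for (pat in c("gaussian_blob", "rectangle_torso", "texture_patch")) {
    sc <- generate_breathing_video(scene_spec(pattern = pat, duration = 5,
                                              delta0 = 0.5))
    expect_true(all(is.finite(sc$video$frames)))
    expect_gt(sd(sc$video$frames[, , 1, 1]), 0.001)  # has texture
    amp <- amp_central(measure_displacement(sc$video), 0.25)
    expect_equal(amp, 0.5, tolerance = 0.1)
  }
})
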