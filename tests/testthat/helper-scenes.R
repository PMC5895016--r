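# Shared fixtures for the heavier pipeline tests. Everything is generated in
# code; expensive runs (full 60 s magnifications) are computed once per test
# session and memoized here so several test blocks can measure the same
# output.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# Amplitude of a periodic component over the central 80% of a trace,
# excluding the temporal filter's warm-up at the ends.
amp_central <- function(trace, freq) {
  v <- trace$values
  n <- length(v)
  idx <- seq(floor(n * 0.1) + 1L, ceiling(n * 0.9))
  tt <- (idx - 1) / trace$fps
  X <- cbind(1, cos(2 * pi * freq * tt), sin(2 * pi * freq * tt))
  cf <- stats::lm.fit(X, v[idx])$coefficients
  unname(sqrt(cf[2]^2 + cf[3]^2))
}

# The standard verification scene: 96 x 96, 10 fps, 60 s, blob moving
# 0.05 px at 0.25 Hz. Deterministic (no noise).
default_scene <- function() fixture("default_scene",
  generate_breathing_video(scene_spec()))

# a short scene for fast structural tests (20 s)
short_scene <- function() fixture("short_scene",
  generate_breathing_video(scene_spec(duration = 20)))

elvm_run <- function(alpha, enforce_bound = FALSE) {
  key <- sprintf("elvm_%g_%d", alpha, enforce_bound)
  fixture(key, magnify_intensity(default_scene()$video,
                                 elvm_config(alpha = alpha,
                                             enforce_bound = enforce_bound)))
}

pbvm_run <- function(alpha) {
  key <- sprintf("pbvm_%g", alpha)
  fixture(key, magnify_phase(default_scene()$video,
                             pbvm_config(alpha = alpha)))
}

measured_amp <- function(video, freq = 0.25, roi = NULL) {
  amp_central(measure_displacement(video, roi), freq)
}

# noisy breathing torso scene: the synthetic analogue of a filmed breathing
# person (large smooth-edged silhouette + sensor noise)
torso_scene <- function() fixture("torso_scene",
  generate_breathing_video(scene_spec(pattern = "rectangle_torso",
                                      noise_sigma = 0.01, seed = 12)))
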