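# Ground-truthed synthetic breathing scenes.
#
# Patterns are closed-form intensity functions (Gaussian blob, smooth-edged
# rectangle via error-function profiles, analytic texture patch), evaluated
# at continuous sub-pixel offsets per frame. There is no interpolation, so a
# 0.05 px translation is rendered exactly — interpolation artifacts would
# contaminate amplification measurements at that scale.

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Specify a synthetic breathing scene
#'
#' The scene is a mostly static frame containing one pattern undergoing
#' sub-pixel periodic translation `delta(t) = delta0 * sin(2 pi f t)`,
#' emulating breathing motion (adults: 12-18 breaths/min = 0.2-0.3 Hz), with
#' optional i.i.d. Gaussian sensor noise and global sinusoidal camera shake.
#'
#' Defaults model the verification scenario used throughout the package: a
#' 96 x 96 px, 10 fps, 60 s grayscale scene (at least 12 breathing cycles)
#' with a compact high-contrast feature — `gaussian_blob` with `sigma` 1 px,
#' the kind of sharp detail (button, fold highlight seen at a few metres
#' with ~1 px optical blur) where sub-pixel breathing motion is actually
#' visible — moving 0.05 px at 0.25 Hz (15 breaths/min).
#'
#' @param width,height Frame size in px.
#' @param fps Frame rate in Hz.
#' @param duration Length in seconds.
#' @param pattern `"gaussian_blob"`, `"rectangle_torso"` or `"texture_patch"`.
#' @param delta0 Motion amplitude in px (>= 0; 0 renders a static subject).
#' @param freq Motion frequency in Hz (must respect Nyquist: freq < fps/2).
#' @param motion_axis `"x"` or `"y"`.
#' @param sigma Gaussian blob sigma, or the error-function edge width of the
#'   rectangle, in px.
#' @param rect_w,rect_h Rectangle dimensions in px (rectangle_torso only).
#' @param extent Texture patch envelope sigma in px (texture_patch only).
#' @param contrast Peak intensity of the pattern above background.
#' @param background Constant background intensity in \[0, 1\].
#' @param cx,cy Pattern centre (px, defaults to the frame centre).
#' @param noise_sigma Std of i.i.d. Gaussian sensor noise on the \[0, 1\]
#'   scale.
#' @param shake_amp,shake_freq Global sinusoidal camera-shake translation
#'   (px, Hz) applied to both axes.
#' @param seed Integer RNG seed for the noise (and texture realization).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 96, height = 96, fps = 10, duration = 60,
                       pattern = c("gaussian_blob", "rectangle_torso",
                                   "texture_patch"),
                       delta0 = 0.05, freq = 0.25, motion_axis = c("x", "y"),
                       sigma = 1, rect_w = 24, rect_h = 36, extent = 10,
                       contrast = 0.6, background = 0.2,
                       cx = (width + 1) / 2, cy = (height + 1) / 2,
                       noise_sigma = 0, shake_amp = 0, shake_freq = 1,
                       seed = 1L) {
  pattern <- match.arg(pattern)
  motion_axis <- match.arg(motion_axis)
  if (delta0 < 0) stop("delta0 must be >= 0")
  if (freq >= fps / 2)
    stop("motion frequency must respect Nyquist: freq < fps/2")
  if (round(duration * fps) < 2) stop("duration * fps must be >= 2 frames")
  if (noise_sigma < 0 || shake_amp < 0) stop("noise/shake must be >= 0")
  structure(as.list(environment()), class = "scene_spec")
}

# Pattern intensity above background, evaluated at a continuous offset.
render_pattern <- function(spec, ox, oy, tex = NULL) {
  X <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  Y <- matrix(seq_len(spec$height), spec$height, spec$width)
  x <- X - spec$cx - ox
  y <- Y - spec$cy - oy
  switch(spec$pattern,
    gaussian_blob = spec$contrast * exp(-(x^2 + y^2) / (2 * spec$sigma^2)),
    rectangle_torso = {
      edge <- function(u, half)
        0.5 * (erf((u + half) / (sqrt(2) * spec$sigma)) -
                 erf((u - half) / (sqrt(2) * spec$sigma)))
      spec$contrast * edge(x, spec$rect_w / 2) * edge(y, spec$rect_h / 2)
    },
    texture_patch = {
      env <- exp(-(x^2 + y^2) / (2 * spec$extent^2))
      waves <- 0
      for (j in seq_len(nrow(tex)))
        waves <- waves + tex[j, "a"] *
          cos(tex[j, "kx"] * x + tex[j, "ky"] * y + tex[j, "phi"])
      spec$contrast * env * waves / sum(abs(tex[, "a"]))
    })
}

# Fixed texture realization drawn from the scene seed.
texture_components <- function(spec, n = 6L) {
  rng <- local({
    set.seed(spec$seed + 7L)
    ang <- stats::runif(n, 0, 2 * pi)
    kmag <- stats::runif(n, 0.3, 1.2)
    cbind(a = stats::runif(n, 0.3, 1), kx = kmag * cos(ang),
          ky = kmag * sin(ang), phi = stats::runif(n, 0, 2 * pi))
  })
  rng
}

scene_offsets <- function(spec, tt) {
  breathing <- spec$delta0 * sin(2 * pi * spec$freq * tt)
  shake <- spec$shake_amp * sin(2 * pi * spec$shake_freq * tt)
  dx <- shake + if (spec$motion_axis == "x") breathing else 0
  dy <- shake + if (spec$motion_axis == "y") breathing else 0
  list(dx = dx, dy = dy, breathing = breathing, shake = shake)
}

#' Generate a ground-truthed breathing video
#'
#' Renders the pattern analytically at the continuous offset delta(t) per
#' frame (no nearest-pixel snapping), adds the optional global shake offset,
#' then i.i.d. Gaussian noise with the spec's sigma and seed. The same seed
#' reproduces the video bit-exactly; the noiseless component is independent
#' of the seed (except the texture pattern, whose realization is part of the
#' scene and is drawn from the seed).
#'
#' @param spec A [scene_spec()].
#' @return A `breathing_scene`: list with `video` ([video_tensor()]), `truth`
#'   (data.frame: frame, time_s, dx, dy, breathing, shake), and `spec`.
#' @export
generate_breathing_video <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  T_ <- round(spec$duration * spec$fps)
  tt <- (seq_len(T_) - 1) / spec$fps
  off <- scene_offsets(spec, tt)
  tex <- if (spec$pattern == "texture_patch") texture_components(spec)
  frames <- array(spec$background, c(spec$height, spec$width, 1L, T_))
  for (t in seq_len(T_))
    frames[, , 1, t] <- frames[, , 1, t] +
      render_pattern(spec, off$dx[t], off$dy[t], tex)
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    frames <- frames + array(stats::rnorm(length(frames), 0,
                                          spec$noise_sigma), dim(frames))
  }
  truth <- data.frame(frame = seq_len(T_), time_s = tt,
                      dx = off$dx, dy = off$dy,
                      breathing = off$breathing, shake = off$shake)
  structure(list(video = video_tensor(frames, spec$fps, "gray"),
                 truth = truth, spec = spec),
            class = "breathing_scene")
}

# conservative half-extent of a pattern, for overlap checks and ROIs
pattern_radius <- function(spec) {
  core <- switch(spec$pattern,
    gaussian_blob = 5 * spec$sigma,
    rectangle_torso = max(spec$rect_w, spec$rect_h) / 2 + 5 * spec$sigma,
    texture_patch = 3 * spec$extent)
  core + spec$delta0 + spec$shake_amp + 1
}

#' Compose several breathing subjects on one canvas
#'
#' Each region is an independently parameterized [scene_spec()] with its own
#' centre (`cx`, `cy`), amplitude, frequency (or `delta0 = 0` for a
#' non-breathing subject). Regions must not overlap. Rendering is additive
#' over a shared constant background, so disjoint composition is exact and
#' order-independent.
#'
#' @param specs List of [scene_spec()]s sharing width/height/fps/duration
#'   (those of the first spec define the canvas).
#' @param noise_sigma,seed Global sensor noise applied to the composed canvas.
#' @return List with `video`, `truths` (list of per-region ground-truth
#'   data.frames), `rois` (per-region `list(x=, y=)` boxes for trace
#'   extraction), and `specs`.
#' @export
generate_multi_subject_scene <- function(specs, noise_sigma = 0, seed = 1L) {
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, TRUE, "scene_spec")))
  base <- specs[[1]]
  T_ <- round(base$duration * base$fps)
  tt <- (seq_len(T_) - 1) / base$fps
  for (sp in specs)
    if (sp$width != base$width || sp$height != base$height ||
        sp$fps != base$fps || sp$duration != base$duration)
      stop("all specs must share canvas dimensions, fps and duration")
  r <- vapply(specs, pattern_radius, 1)
  if (length(specs) > 1L) {
    for (i in seq_along(specs)) for (j in seq_along(specs)) {
      if (i >= j) next
      if (abs(specs[[i]]$cx - specs[[j]]$cx) < r[i] + r[j] &&
          abs(specs[[i]]$cy - specs[[j]]$cy) < r[i] + r[j])
        stop("regions ", i, " and ", j, " overlap")
    }
  }
  frames <- array(base$background, c(base$height, base$width, 1L, T_))
  truths <- vector("list", length(specs))
  rois <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    off <- scene_offsets(sp, tt)
    tex <- if (sp$pattern == "texture_patch") texture_components(sp)
    for (t in seq_len(T_))
      frames[, , 1, t] <- frames[, , 1, t] +
        render_pattern(sp, off$dx[t], off$dy[t], tex)
    truths[[i]] <- data.frame(frame = seq_len(T_), time_s = tt,
                              dx = off$dx, dy = off$dy,
                              breathing = off$breathing, shake = off$shake)
    rr <- ceiling(r[i])
    rois[[i]] <- list(x = c(max(1, round(sp$cx) - rr),
                            min(base$width, round(sp$cx) + rr)),
                      y = c(max(1, round(sp$cy) - rr),
                            min(base$height, round(sp$cy) + rr)))
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    frames <- frames + array(stats::rnorm(length(frames), 0, noise_sigma),
                             dim(frames))
  }
  list(video = video_tensor(frames, base$fps, "gray"),
       truths = truths, rois = rois, specs = specs)
}
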