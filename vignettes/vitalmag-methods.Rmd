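---
title: "Methods: Eulerian and phase-based video magnification in vitalmag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Eulerian and phase-based video magnification in vitalmag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalmag)
```

## The problem and the model

A breathing adult moves at 0.2–0.3 Hz (12–18 breaths/min). Filmed from a few
metres, that motion is commonly well under one pixel — invisible to the eye
and to naive frame differencing. `vitalmag` magnifies it Eulerian-style: it
never tracks points, but amplifies the *temporal* variation observed at
fixed pixel locations inside a chosen temporal frequency band.

Write a translating intensity profile as $I(x,t) = f(x + \delta(t))$. Both
pipelines aim to synthesize $\hat I(x,t) = f(x + (1+\alpha)\,\delta(t))$ for
a user gain $\alpha$, but differ in the spatial representation they amplify.

**Intensity path (ELVM).** To first order,
$\hat I = I + \alpha\,\delta(t)\,\partial I/\partial x$, and the term
$\delta(t)\,\partial I/\partial x$ is exactly what a temporal bandpass
extracts from a translating scene. The pipeline builds a Laplacian pyramid
per frame and channel, bandpasses every band's pixel series along time,
scales the filtered signal by a per-band $\alpha_k$ and adds it back, then
collapses the pyramid. The linearization is trusted only while
$(1+\alpha)\,\delta \le \lambda/8$ for a band of spatial wavelength
$\lambda$; beyond it the synthesized motion saturates and rings.

**Phase path (PBVM).** A complex steerable pyramid gives every location a
local amplitude and phase per (scale, orientation). By the Fourier shift
theorem a translation is a phase change, so the pipeline computes each
coefficient's phase difference against frame 0, bandpasses those difference
series, multiplies by $\alpha$, and rotates the coefficients:
$\hat S_\omega = S_\omega e^{i\alpha B_\omega}$. Amplitudes — where sensor
noise mostly lives — are never modified, which is why the phase path
tolerates much larger $\alpha$; its own per-band limit scales as $1/\omega$
(and doubles when the 8-orientation, half-octave pyramid replaces the
4-orientation octave one).

Both pipelines assume a *mostly static scene* (frame 0 is a valid
reference), motion small relative to the pattern scale, and a frame rate
satisfying Nyquist for the passband's upper edge ($f_h < f_s/2$); the
toolkit refuses configurations violating the latter.

## Spatial decompositions

The Gaussian/Laplacian pyramid uses the separable 5-tap binomial kernel
[1,4,6,4,1]/16 with whole-sample reflect boundaries. Downsampling keeps odd
indices (length $\lceil n/2\rceil$, so odd sizes are exact); upsampling
zero-stuffs and blurs with the doubled kernel, targeting the recorded
partner shape. Band $k$ is $G_k - \mathrm{up}(G_{k+1})$ and the coarsest
Gaussian level is kept, so collapse is an exact inverse (tested to
$10^{-10}$, in practice machine-exact).

Each pyramid element carries a representative wavelength $\lambda_k$: the
lowpass residual — the lowest-frequency element — takes (frame diagonal)/3,
halving per finer band, the convention of the reference Eulerian
implementation. These $\lambda_k$ drive two per-band controls:

- `band_alpha(alpha, lambda_k, lambda_c)` — the linear attenuation ramp
  $\alpha_k = \alpha\,\lambda_k/\lambda_c$ below a cutoff wavelength
  (`lambda_c = 0` disables it);
- `alpha_bound(lambda_k, delta)` $= \lambda_k/(8\delta) - 1$ — the
  first-order validity cap, enforced by default with an assumed scene
  motion `delta_assumed` of 0.1 px, the order of magnitude of
  breathing-induced image motion at a few metres. A 1 px assumption would
  cap every band near $\alpha \approx 5$ at typical frame sizes and make
  the useful range $\alpha = 5\ldots60$ unreachable, contradicting how the
  method is used; the cap is a guard rail, not a hidden gain control, and
  `enforce_bound = FALSE` exposes the raw amplifier.

ELVM amplifies *every* element including the lowpass residual (with its own
$\lambda$): for smooth scenes most motion energy lives there, and leaving it
unamplified silently caps the achievable magnification.

The steerable pyramid is built in the frequency domain: raised-cosine (in
log-radius) radial windows split scales, and $\cos^{K-1}$ angular windows
supported on a half-plane give $K$ analytic (complex) orientation bands per
scale. The windows are normalized so that the squared filters tile the
spectrum exactly; reconstruction multiplies by the conjugate filters,
restores Hermitian symmetry and adds the real high- and low-pass residuals,
and is machine-exact for untouched coefficients (the 40 dB acceptance
threshold is passed with ~300 dB). Scale $s$ is decimated by cropping the
centred spectrum — lossless on the band's support — with a scale factor
that keeps downsampled intensities on the input scale. Default depth leaves
the coarsest grid at ≥ 4 px per side: structure left in the never-amplified
lowpass residual is structure whose motion cannot be magnified, so the
pyramid is made as deep as the image allows.

Residuals pass through unamplified in PBVM (phase is meaningless for the
real residual images). This is the phase path's main systematic loss: the
sharper the pattern, the more motion-relevant energy sits in the high-pass
residual, and measured amplification lands some 10–25 % below the nominal
$(1+\alpha)$ on the test scenes. The tests budget for this explicitly.

## Temporal filtering

The bandpass is a digital Butterworth (maximally flat passband, monotonic
response), order 1 by default — the classic choice for Eulerian
magnification, with gentle band edges and short transients. Since the
pipeline is offline, the filter is applied forward–backward (zero phase):
phase lag would shift the apparent motion in time. Edges are stabilized by
odd-reflect padding of $3\times$ the coefficient length plus steady-state
initial conditions; the application is vectorized across all pixels of a
band at once. An ideal FFT brick-wall bandpass is available behind
`method = "ideal"` as a cross-check oracle, and the test suite compares the
two on mixed-tone signals. DC is removed by construction (gain $< 10^{-3}$
at 0 Hz); IIR edge transients leave a residual mean below 1 % of the signal
scale, which the warm-up-aware measurement protocol (below) avoids.

PBVM filters the *phase-difference* series, which are real and wrapped to
$(-\pi,\pi]$; differences are computed as $\arg(c_t\,\bar c_{\mathrm{ref}})$
— wrap-safe by construction, never by subtracting raw angle arrays.

## Measurement tools

`measure_displacement` is the independent motion oracle: per frame, the
translation of a region against frame 1 via Fourier-domain correlation with
matrix-DFT upsampled peak refinement (window ±1 px, step 0.01 px). The DC
bin is zeroed, so a constant background cannot bias it. The default
spectral weighting is the cross-power magnitude (matched filter): whitened
classic phase correlation is available (`weight = "phase"`) but weights all
frequencies equally, which is noisy and biased on smooth scenes whose upper
spectrum carries no signal. Static scenes measure below 0.01 px; a
constructed 3 px shift measures 3.00 ± 0.01.

Amplitudes are extracted by least-squares sinusoid fit at the known scene
frequency over the central 80 % of the trace, excluding the filter's
warm-up at both ends.

MSE is computed on the 0–255 scale per frame and channel, channels averaged
(arithmetic mean over R, G, B), frames averaged; PSNR
$= 10\log_{10}(255^2/\mathrm{MSE})$ in dB (base-10 log, as the dB definition
requires), with an `Inf` sentinel for identical videos.

`estimate_breath_rate` detrends (mean + linear), Hann-tapers, and takes the
periodogram peak within 0.1–0.5 Hz; a peak is reported only when its power
is ≥ 4× the median in-band power, otherwise the result is explicitly "no
respiration detected". A 60 s trace gives 1 breath/min resolution.

## The synthetic scenes: what they emulate, and what they do not

Patterns are closed-form intensity functions — Gaussian blob, smooth-edged
rectangle (error-function profiles), analytic texture patch — evaluated at
continuous offsets, so a 0.05 px translation is rendered exactly;
interpolation artifacts would swamp amplification measurements at that
scale. Defaults (chosen once as the standard verification conditions): a
96 × 96 px, 10 fps, 60 s grayscale scene — small enough for seconds-scale
tests, long enough for ≥ 12 breathing cycles and 1 bpm spectral resolution
— containing a blob of σ = 1 px moving 0.05 px at 0.25 Hz. The small σ
mirrors the sharp, high-contrast details (a button, a fold highlight seen
through ~1 px of optical blur) where sub-pixel breathing motion actually
becomes visible in real footage; on large smooth regions both methods
behave almost identically and the comparison is uninformative. Sensor noise
is i.i.d. Gaussian with σ = 0.01 (≈ 2.5/255, a good-light CMOS level);
camera shake is a global sinusoidal translation — the minimal model of the
tripod-vibration confound, provided to demonstrate (not fix) shake-induced
false magnification. The quality-comparison scene is the smooth-edged
breathing rectangle ("torso") plus noise: the closest analogue of a filmed
breathing person, where the phase path's large magnified motion dominates
its MSE and the intensity path, whose response the per-band bound keeps
small, stays closer to the input.

Real footage differs in ways these scenes deliberately ignore: illumination
flicker and shadows, non-rigid and non-periodic motion, codec compression,
spatially correlated sensor noise, and multiple motion sources overlapping
in space. Passing the synthetic suite shows the *machinery* is correct and
calibrated; it does not certify performance on arbitrary real video.

## Numerical choices and degenerate inputs

- Intensities live on real-valued [0, 1] throughout; clipping and 8-bit
  quantization happen only at PNG export, never during processing
  (amplification legitimately overshoots transiently).
- Zero coefficients get phase 0 by convention; phases lie in $(-\pi,\pi]$.
- $\delta = 0$ makes both amplification bounds $+\infty$ (no motion, no
  constraint); non-positive $\lambda$ or $\omega$ are errors.
- A flat ROI (zero variance) is a degenerate input for the displacement
  oracle and errors out rather than returning noise.
- A constant trace reports "no respiration detected" rather than a rate.
- Upsampled-correlation ties resolve to the first maximum; with the 0.01 px
  grid this is below every tolerance used.
- Laplacian perfect reconstruction is asserted at $10^{-10}$; steerable
  fidelity at 40 dB PSNR; both hold with orders of magnitude to spare.

## Problem sizes

Verification runs use 96 × 96 px (single-subject) and 192 × 64 / 192 × 96 px
(multi-subject) scenes at 10 fps for 60 s (600 frames), with 64 × 64 images
for pyramid round-trip batteries and 20 s scenes for structural tests —
sizes at which the full suite and the acceptance script each complete in
minutes on one CPU while keeping ≥ 12 motion cycles and 1 bpm rate
resolution.

## Known limitations

- No compressed-container I/O: videos are exchanged as lossless PNG
  sequences with an fps sidecar (codec-free and bit-exact by design).
- The phase reference is frame 0; very long or drifting recordings would
  need a sliding reference, which is out of scope.
- No amplitude-weighted phase smoothing and no Riesz/real-time variants.
- Camera shake inside the passband is amplified like any other in-band
  motion — the generator exists to demonstrate exactly that failure mode;
  stabilization is explicitly not attempted.
- Color channels are processed independently (no luminance/chrominance
  transform), so chroma noise is amplified like luma noise.
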