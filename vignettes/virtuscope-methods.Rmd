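---
title: "virtuscope: simulator models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{virtuscope: simulator models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtuscope)
```

`virtuscope` is built around one idea: every instrument-control algorithm a
motorised microscope needs can be validated by *parameter recovery* against
a simulator whose imperfections are known exactly. This vignette documents
the simulator's models, the estimators layered on top of them, the
numerical choices that were genuinely open, and what the passing test suite
does and does not demonstrate about real hardware.

## The virtual instrument

### Synthetic samples

`generate_sample(seed, density, shape)` builds the ground-truth scene: a
mid-grey field (`0.5`) plus two convolved impulse fields — coarse blobs
(Gaussian kernel, σ = 2.5 px) and fine speckle (σ = 0.8 px) — whose
impulse counts scale linearly with `density` ∈ [0, 1]. Three colour
channels share the same structure with per-channel contrast weights
(1, 0.85, 0.7), so they are correlated but not identical, as in a stained
specimen. `density = 0` is an exactly uniform field used for flat-field
work. Generation runs under an isolated RNG stream: the same
`(seed, density, shape)` reproduces the array bit-for-bit and the session's
`.Random.seed` is untouched.

The generator emulates the two regimes that matter to the algorithms —
feature-dense scenes (plenty of high-spatial-frequency content for
sharpness metrics and phase correlation) and sparse or blank scenes (the
documented failure mode of the byte-size focus metric, and the input for
shading calibration). It does *not* emulate photon or read noise, Bayer
demosaicing artefacts, illumination drift, or specimen motion; passing
tests therefore show algorithmic correctness under geometric and optical
imperfections, not robustness to sensor noise.

### Stage: dead-band backlash, jitter, hidden affine

The stage holds integer commanded positions and a real-valued mechanism
position `y` per axis with the dead-band invariant `c − b ≤ y ≤ c`
(`c` commanded, `b` backlash). A move to `c'` applies
`y' = min(max(y, c' − b), c')`: sustained travel in one direction is 1:1,
and the first `b` steps after a reversal take up slack and produce no
motion. The initial slack state defaults to "taken up in +"
(`y = c − b`), and is configurable. Optional per-move Gaussian jitter
(σ in steps, clamped at 6σ, drawn from the stage's own seeded stream) is
*transient* — it perturbs the current effective position without random
walking, modelling vibration and encoder-free settling rather than drift.

The stage also carries `true_affine`, the hidden 2 × 2 matrix of camera
pixels per motor step used by the renderer. It is ground truth for tests;
no estimator reads it.

### Camera: sphere-cap focus, defocus blur, vignetting, fixed-quality JPEG

Frames are bilinear crops of the sample at the stage's effective position
mapped through `true_affine` (camera x rightward, y downward, origin
top-left; a `+s`-step move displaces imaged content by `A·s` pixels). Three
imperfections are applied:

* **Sphere-cap focal surface.** Flexure stages swing the sample over a
  spherical cap, so lateral position couples into focus. To first order the
  in-focus z is offset parabolically:
  `z_defocus = z − z_focus − r_px² / (2 · focal_radius · step_scale)`, with
  `r_px` the field centre's lateral offset in pixels and
  `step_scale = √|det A|`. The default `focal_radius = Inf` (flat) keeps
  the imperfections orthogonal in tests; finite radii activate the
  coupling.
* **Defocus blur.** Gaussian, σ = `blur_per_step · |z_defocus|` px
  (default 0.05 px/step), rendered with a 3σ margin before cropping so
  blur has no edge artefacts.
* **Vignetting.** Radial gain `V(r) = 1 − α (r/r_max)²` with `r_max` the
  centre-to-corner distance — the smooth single-coefficient model of the
  illumination falloff low-cost camera modules show.

Every frame is encoded as baseline JPEG at one fixed quality (default 75),
emulating a stream with bit-rate control disabled; the encoded byte count
is the fast focus metric. Exposure is a linear gain `shutter_speed / 17 ms`
clipped to [0, 1]. Rendering is deterministic: identical state produces
bit-identical encoded frames.

Defaults (120 × 160 px frames, z* = 500 steps, 0.05 px/step blur) are
arbitrary in the absence of published hardware constants and are chosen so
that a ±150-step sweep spans clearly-sharp to clearly-blurred; they are
stated here once and not tuned per test.

## Image metrics

**Greyscale** uses the ITU-R BT.601 luma weights (0.299, 0.587, 0.114);
the weights sum to one, so constants are preserved and the output stays in
[0, 1].

**Laplacian sharpness** is `Σ (L ∗ I)⁴` with the 4-neighbour kernel,
summed over the interior (valid) region only. Interior-only summation was
chosen over padded variants because padding breaks two properties the
metric should have — a constant image scores exactly zero, and adding a
constant changes nothing — while the fourth power emphasises strong edges
over low-amplitude noise. Consequences: invariance under constant shift,
exact `s⁴` scaling, and monotone decrease with blur.

**Displacement measurement** is phase correlation: Hann-windowed,
mean-subtracted images; whitened cross-power spectrum; band-limited to the
lower 60% of each frequency axis; integer peak from the inverse FFT; then
sub-pixel refinement by evaluating the inverse DFT on a 1/32-px grid
within ±1 px of the peak (a local matrix-multiply DFT). Two of these
choices were driven by measurement: plain parabolic peak interpolation
left biases up to ~0.23 px at half-pixel fractions on moderately textured
scenes, and unmasked whitening amplified interpolation/compression noise
in the highest frequencies; band-limiting plus upsampled refinement brings
the worst-case error under 0.1 px for shifts up to a quarter frame, which
is the accuracy the calibration and closed-loop layers assume.
Confidence is the peak-to-sidelobe ratio (peak over the 99.5th percentile
of the correlation surface outside a ±5 px exclusion zone); below 4 the
measurement raises a low-confidence error rather than returning a guess —
calibration aborts cleanly on featureless scenes.

## Autofocus

The coarse procedure captures `n_planes` equally spaced frames across
`[z_min, z_max]`, scores each with the Laplacian metric and moves to the
arg-max plane. Ties break to the first plane visited (deterministic); an
all-tie sweep (blank field) is flagged `zero_contrast`. The sweep range is
a required caller argument — there is no principled way to pick "far above
and below focus" without knowing the specimen, so the package does not
guess.

The fast procedure sweeps z in fine steps (default 10), recording encoded
byte sizes, smooths with a centred 5-sample moving average (smoothing
window: small enough to keep the peak, large enough to kill per-frame
quantisation jitter), locates the maximum and refines it with a parabola
through the three surrounding samples. If the smoothed maximum sits at
either end of the sweep, the curve is monotone and the procedure reports
focus-not-found instead of extrapolating. The return move approaches the
peak from below so the z dead band is crossed in a consistent direction:
the sweep itself ran upward, so sweep and return share the same slack
state and the achieved physical height matches the measured optimum even
on a stage with z backlash. On sparse scenes the byte-size metric may peak
off focus (blur spreads information into otherwise-empty compression
blocks); the test suite asserts the dense-scene contract and includes a
sparse-scene case that is only required not to crash.

## Calibration

### Camera–stage mapping and backlash

Per axis: a 64-step take-up move absorbs unknown initial slack (dead bands
up to 64 steps are supported); an 8-step probe measures px-per-step so the
schedule adapts to the unknown magnification; then steps double from
`max(4, max_px/(4·pps))` until the next doubling is predicted to exceed a
quarter of the smaller frame dimension, padded with repeats of the final
size to at least four moves per direction (keeps the fits over-determined
under noise). The same schedule is then run in reverse (one reversal).

Estimation, in cumulative coordinates projected onto the axis's motion
direction: the `+`-phase slope gives px/step; the dead band offsets the
whole `−`-phase line by `slope · b`, so `b` is the intercept separation
over the slope. Because a dead band larger than the biggest single step is
consumed across *several* reversal moves, points inside the consumption
zone lie off the offset line; the estimator first gets an endpoint
difference guess `b₀ = commanded reversal travel − measured travel`, then
refits the two-intercept model using only `−` points whose cumulative
reversal travel exceeds `b₀`. The affine column is an unweighted
least-squares fit of per-move displacement vectors against
dead-band-corrected effective steps. One move per direction per step size
is measured (no repeats averaged); repeats are the natural extension if a
noisier camera demands them.

Recovery performance under the study conditions (0.5 px equivalent jitter,
well-conditioned random affines): median per-element relative error ≈ 0.5%,
backlash error a fraction of a step across dead bands 0–40 steps —
comfortably inside the 2% / 1-step envelopes the tests assert.

### Flat field

From a blank-sample frame, a 12 × 16 per-channel gain grid is computed as
`reference / cell mean`, the per-channel reference being the brightest
cell mean (so gains are ≥ 1 on a vignetted frame and exactly 1 on a flat
one). Application bilinearly upsamples the grid anchored at cell centres
with *linear extrapolation* beyond the outer centres — clamping instead
flattens the correction exactly where the profile falls fastest and left
~1.1% residual CV; extrapolation brings the corrected CV of an α = 0.5
vignetted frame to ~0.3%. Cells darker than 0.02 abort with a
degenerate-input error rather than emitting huge gains. The grid is coarse
by design, mirroring in-pipeline lens-shading tables.

### Closed-loop translation

`closed_loop_move()` converts the remaining pixel error through `A⁻¹`,
commands integer steps, re-measures the achieved displacement from frames
and iterates (default tolerance 1 px, 5 iterations). Corrections larger
than a quarter frame are executed as sub-hops with a capture per hop so
every individual measurement stays in phase correlation's reliable range;
measured displacement accumulates across hops. During a scan the *target*
for each site is expressed in cumulative pixels from the scan origin, so
per-site residuals do not compound — the property the paired open-loop
comparison makes visible: on a 15-step-backlash stage an open-loop snake
scan is ~15 px off after every row reversal, while the closed-loop run
stays within the tolerance at every one of the 100 sites.

## Data collection

Captures render a frame, serialise a versioned metadata document
(`virtuscope/1`: camera settings, stage position, calibration snapshot,
user keys) to JSON and embed it in the JPEG's EXIF `UserComment` tag (APP1
segment, little-endian TIFF body, the standard 8-byte `UNICODE\0` prefix;
written and parsed by the package since no installed R package edits
EXIF). Scans write one sub-directory per scan with zero-padded site
indices, and persist incrementally: cancellation is honoured at
cooperative checkpoints, so an aborted scan leaves exactly the completed
sites on disk, every file independently decodable.

## The Web-of-Things layer

Properties are read with GET and written with PUT on
`/properties/<name>`; actions are invoked with POST and answered `201`
immediately with a pollable record at `/action-records/<id>`
(`pending → running → completed | cancelled | error`; DELETE requests
cancellation). The Thing Description (minimal W3C vocabulary: title,
security, typed properties/actions, one form per interaction) and an
OpenAPI 3.0.3 document are generated from the registry, so they cannot
drift from what is actually served. Extensions register bundles of
actions/properties under `/extensions/<name>/…` through the same mechanism
the built-in autofocus, calibration and scan bundles use — any of them can
be disabled at boot.

**Concurrency model.** R is single-threaded, so the threaded design of
networked instrument servers is realised cooperatively: one action runs at
a time and yields at *checkpoints*, where the server pumps pending
requests (reads, cancellations, stream frames) before the action resumes.
The observable contract is that of a threaded server — property reads stay
live during a long scan, a conflicting move is refused with 409 naming the
held re-entrant lock, aborts land at site boundaries — and that contract,
not the scheduling primitive, is what the tests pin down. One consequence
is documented rather than hidden: a "wait briefly for the lock" grace
period degenerates to immediate denial, because the holder cannot progress
while the requester waits.

Action records are garbage-collected beyond a retention capacity
(default 100 terminal records). MJPEG streaming keeps a single latest-frame
buffer with a monotone index; each client tracks the last index it was
given, so clients never receive a frame twice and a slow client simply
receives a subsequence — bounded latency, no queueing. The HTTP layer
itself (request parsing, responses, multipart streaming, and the client
side) is a minimal HTTP/1.1 implementation over base R sockets.

## Problem sizes and verification

The test-suite and acceptance-script sizes are the study conditions: 20
random affines / 20 seeds for the recovery suites, 11-plane coarse and
31-frame fast autofocus sweeps, a 10 × 10 closed- vs open-loop scan on
1536² scenes, 120 × 160 px frames throughout. These sizes give stable
medians while keeping a full run in minutes on one CPU. Every number in
this vignette and the README is produced by the package's own tests or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## Known limitations

* No sensor-noise, demosaic, rolling-shutter or illumination-drift models;
  recovery margins on real cameras will be wider.
* The backlash model is a pure dead band — no compliance, hysteresis
  curvature, or load dependence — and calibration assumes the dead band is
  smaller than the take-up move (64 steps).
* The sphere-cap coupling is first-order (parabolic) and axially
  symmetric.
* The cooperative scheduler serialises actions; it cannot express two
  genuinely simultaneous hardware motions (nor should it — the locks exist
  to forbid exactly that), and denied requests are never queued.
* The WoT dialect is a pragmatic subset: no events, no Server-Sent Events,
  no security schemes beyond `nosec`, empty semantic-type annotations;
  mDNS announcement is accepted as a config flag but not implemented.
* The HTTP server handles one connection at a time and is intended for
  simulation, testing and local scripting, not production deployment.
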