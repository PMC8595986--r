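# virtuscope

A fully simulatable motorised light microscope for R, with the control
algorithms and the networked control surface used by open-hardware
microscopes.

Automated microscopes built around low-cost flexure stages and camera
modules need a stack of instrument-control algorithms — autofocus that runs
at every site of a large tile scan, flat-field correction for a strongly
vignetting camera, a calibration that maps motor steps to camera pixels and
measures mechanical backlash, and closed-loop stage translation that stops
positioning errors accumulating over hundreds of fields of view. Developing
and testing those algorithms on hardware is slow and unreproducible.
`virtuscope` provides a *virtual* instrument with known ground truth — a
three-axis stage with a dead-band backlash model and a hidden steps→pixels
affine, a camera with vignetting, defocus blur and a curved (sphere-cap)
focal surface — so that every algorithm is testable by parameter recovery:
run the procedure, compare what it estimated with what the simulator knows.

The instrument is exposed the way real networked lab devices are: a
Web-of-Things interaction model (properties read/written over HTTP verbs,
long-running actions as pollable background records guarded by re-entrant
hardware locks, a Thing Description and an OpenAPI document, MJPEG frame
streaming, an extension mechanism) with both an HTTP/1.1 server and a
scripting client that turns the device's capabilities into native R
functions.

## The algorithms

**Laplacian autofocus.** Frames from a z-stack are converted to greyscale
(BT.601 weights), convolved with the 4-neighbour Laplacian
`[[0,1,0],[1,−4,1],[0,1,0]]`, and scored by `Σ (L ∗ I)⁴` over the interior;
the stage returns to the arg-max plane.

**JPEG-size autofocus.** With bit-rate control disabled every stream frame
is compressed at the same quality, so the encoded byte size peaks when fine
detail is sharpest. Sweeping z without stopping while recording
`(z, bytes)`, smoothing with a 5-sample moving average and refining the
peak with a parabolic fit gives sub-step focus in a fraction of the frames
a full z-stack needs. On sparse samples the metric can peak away from
focus; it is reliable on feature-dense ones.

**Camera–stage calibration.** For each axis: take up slack, probe the
magnification, then move in geometrically increasing steps forwards and the
same schedule backwards, measuring each image displacement by
phase correlation (Hann window, band-limited whitening, upsampled-DFT
sub-pixel refinement). A shared-slope fit of cumulative displacement
against commanded position, with separate intercepts for the two
directions, yields the affine column and the backlash
`b = Δintercept / slope` — motion in opposite directions is offset by
exactly one dead band. The camera's coordinate system is ground truth.

**Closed-loop translation.** The same displacement measurement acts as a
2-D encoder: command `A⁻¹·(remaining error)`, re-measure, iterate (≤ 5
iterations, 1 px tolerance). Errors stop accumulating across a scan.

**Flat-field correction.** From a frame of a blank sample, a coarse
per-channel gain grid (`reference / local mean`) is estimated and
bilinearly upsampled onto frames, flattening the vignetting profile
`V(r) = 1 − α (r/r_max)²`.

## Worked example

```r
library(virtuscope)

scope <- virtual_microscope(density = 0.8, seed = 42,
                            backlash = c(15, 15, 0))
scope$move_to(c(0, 0, 460))              # start away from focus (z* = 500)

af <- fast_autofocus(scope, z_range = 300, step = 10)
af
#> <autofocus/fast: best_z = 500.0 steps, 31 planes, metric jpeg_size>

cal <- calibrate_camera_stage(scope)
cal
#> <camera-stage calibration>
#>   A (px/step):
#>      [,1]   [,2]
#> [1,]    1 0.0000
#> [2,]    0 0.9988
#>   backlash: (15.00, 15.00) steps; residual RMS 0.007 px
```

The hidden truth was the identity affine and 15 steps of backlash on x and
y: the calibration recovered the matrix to a fraction of a percent and the
dead band to a fraction of a step, using nothing but rendered frames.

Serving the same instrument over HTTP and scripting it:

```r
thing <- build_microscope_thing(scope)
# run_server(thing, port = 9393)          # in a server process
proxy <- connect(thing)                   # or connect("http://host:9393")
proxy$get_property("shutter_speed")       # 17  (milliseconds)
proxy$set_property("shutter_speed", 22)
proxy$actions$move(x = 100, y = 0, z = 500)
```

A command-line front end (`inst/cli/virtuscope.R`) wraps `serve`,
`autofocus`, `calibrate`, `scan` and `displacement` subcommands around the
same functions.

## Methods

The methods vignette (`vignettes/virtuscope-methods.Rmd`) documents the
simulator's models and their parameters, the estimator designs, numerical
choices and known limitations.
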