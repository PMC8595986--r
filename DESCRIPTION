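Package: virtuscope
Title: Virtual Motorised Microscope with Web-of-Things Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A fully simulatable motorised light microscope: a virtual
    three-axis stage with mechanical backlash and a virtual camera with
    vignetting, defocus blur and a curved (sphere-cap) focal surface,
    rendered from deterministic synthetic samples. On top of the simulator
    the package implements the instrument-control algorithms used by
    open-hardware microscopes: Laplacian and JPEG-frame-size autofocus,
    flat-field (lens shading) correction, camera-stage affine and backlash
    calibration, closed-loop image-feedback translation, and metadata-rich
    tiled scanning. The instrument is exposed through a Web-of-Things style
    interaction model (properties, background actions with re-entrant
    hardware locks, Thing Description and OpenAPI documents, MJPEG frame
    streaming) with both an HTTP server and a scripting client, so that
    every algorithm can be tested end-to-end by parameter recovery against
    the simulator's ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    R6,
    jsonlite,
    EBImage,
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    parallel
Config/testthat/edition: 3
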