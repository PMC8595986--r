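#' Virtual motorised microscope
#'
#' Bundles a [VirtualStage], [VirtualCamera] and a synthetic sample into the
#' instrument interface the control algorithms (autofocus, calibration,
#' scanning) and the Web-of-Things server operate on. All higher-level code
#' talks to this object only through `move_to()` / `move_rel()`,
#' `position()` and `grab_frame()`, so the same algorithms would drive real
#' hardware exposing the same surface.
#' @export
VirtualMicroscope <- R6::R6Class("VirtualMicroscope",
  public = list(
    #' @field stage The [VirtualStage].
    stage = NULL,
    #' @field camera The [VirtualCamera].
    camera = NULL,
    #' @field sample The `vs_sample` currently on the stage.
    sample = NULL,
    #' @field calibration Last [calibrate_camera_stage()] result, or `NULL`.
    calibration = NULL,
    #' @field flat_field Last [compute_flat_field()] table, or `NULL`.
    flat_field = NULL,
    #' @field frames_rendered Running count of rendered frames.
    frames_rendered = 0L,

    #' @description Assemble a microscope.
    #' @param sample `vs_sample`; default a dense sample.
    #' @param stage `VirtualStage`; default ideal (no backlash, no jitter).
    #' @param camera `VirtualCamera`; default 120 x 160 px.
    initialize = function(sample = generate_sample(1L, 0.8),
                          stage = VirtualStage$new(),
                          camera = VirtualCamera$new()) {
      self$sample <- sample
      self$stage <- stage
      self$camera <- camera
    },

    #' @description Absolute stage move.
    #' @param target `(x, y, z)` integer steps.
    #' @param holder Optional lock-holder label for the command log.
    move_to = function(target, holder = NA_character_) {
      self$stage$move_to(target, holder = holder); invisible(self)
    },

    #' @description Relative stage move.
    #' @param delta `(dx, dy, dz)` integer steps.
    #' @param holder Optional lock-holder label for the command log.
    move_rel = function(delta, holder = NA_character_) {
      self$stage$move_rel(delta, holder = holder); invisible(self)
    },

    #' @description Commanded stage position, integer steps.
    position = function() self$stage$commanded(),

    #' @description Render a frame at the current position.
    grab_frame = function() {
      self$frames_rendered <- self$frames_rendered + 1L
      fr <- render_frame(self$camera, self$stage, self$sample)
      if (!is.null(self$flat_field))
        fr$pixels <- apply_flat_field(fr, self$flat_field)
      fr
    },

    #' @description Render a frame and return its greyscale pixel matrix.
    grab_gray = function() to_grayscale(self$grab_frame()$pixels)
  )
)

#' Construct a virtual microscope in one call
#'
#' Convenience constructor used throughout the examples and tests.
#'
#' @param density Sample feature density in `[0, 1]`.
#' @param seed Sample (and stage jitter) seed.
#' @param sample_shape Sample `(height, width)` px.
#' @param backlash Per-axis dead band, steps.
#' @param jitter_sigma Stage jitter sigma, steps.
#' @param true_affine Hidden ground-truth 2x2 px/step matrix.
#' @param frame_shape Camera frame `(height, width)` px.
#' @param z_focus In-focus z at the field centre, steps.
#' @param blur_per_step Defocus blur, px per step.
#' @param vignette_alpha Vignetting coefficient.
#' @param focal_radius Sphere-cap radius, steps.
#' @param jpeg_quality Fixed JPEG quality.
#' @return A [VirtualMicroscope].
#' @examples
#' scope <- virtual_microscope(density = 0.8, seed = 42)
#' scope$move_to(c(0, 0, 500))
#' f <- scope$grab_frame()
#' f$byte_size
#' @export
virtual_microscope <- function(density = 0.8, seed = 1L,
                               sample_shape = c(1024, 1024),
                               backlash = c(0, 0, 0), jitter_sigma = 0,
                               true_affine = diag(2),
                               frame_shape = c(120, 160), z_focus = 500,
                               blur_per_step = 0.05, vignette_alpha = 0,
                               focal_radius = Inf, jpeg_quality = 75) {
  VirtualMicroscope$new(
    sample = generate_sample(seed, density, sample_shape),
    stage = VirtualStage$new(backlash = backlash, jitter_sigma = jitter_sigma,
                             true_affine = true_affine, seed = seed),
    camera = VirtualCamera$new(frame_shape = frame_shape, z_focus = z_focus,
                               blur_per_step = blur_per_step,
                               vignette_alpha = vignette_alpha,
                               focal_radius = focal_radius,
                               jpeg_quality = jpeg_quality)
  )
}
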