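#' Build the microscope Thing
#'
#' Wires a [VirtualMicroscope] and a [CaptureStore] into a [Thing]: core
#' properties (`shutter_speed`, read-only `stage_position`, `frame_shape`,
#' `jpeg_quality`) and core actions (`move`, `capture`), plus the default
#' extensions — `autofocus` (`autofocus_coarse`, `autofocus_fast`),
#' `calibration` (`calibrate_camera_stage` and the read-only
#' `camera_stage_mapping` property) and `scan` (`tile_scan`, `zstack`) —
#' each registered through the same [Thing]`$register_extension()`
#' mechanism available to user extensions, so any of them can be disabled
#' or replaced.
#'
#' All hardware-touching actions declare the `stage` and/or `camera` locks;
#' a conflicting invocation is refused with HTTP 409 naming the held lock.
#' Long moves execute in chunks with checkpoints so cancellation and
#' liveness apply to them like any other background action.
#'
#' @param scope A [VirtualMicroscope].
#' @param store A [CaptureStore] (created in a temp directory by default).
#' @param title Device title.
#' @param extensions Which default extensions to register.
#' @return A [Thing].
#' @examples
#' thing <- build_microscope_thing(virtual_microscope(seed = 1))
#' resp <- thing$handle("GET", "/properties/shutter_speed")
#' resp$json  # 17 (milliseconds)
#' @export
build_microscope_thing <- function(scope, store = CaptureStore$new(),
                                   title = "virtuscope microscope",
                                   extensions = c("autofocus", "calibration",
                                                  "scan")) {
  thing <- Thing$new(title = title, scope = scope, store = store)

  thing$add_property("shutter_speed",
    getter = function() scope$camera$shutter_speed,
    setter = function(v) {
      if (!is.numeric(v) || length(v) != 1 || v <= 0)
        stop("shutter_speed must be a positive number of milliseconds",
             call. = FALSE)
      scope$camera$shutter_speed <- as.numeric(v)
    },
    type = "number",
    description = "Camera exposure time in milliseconds")

  thing$add_property("stage_position",
    getter = function() {
      p <- scope$position()
      list(x = p[1], y = p[2], z = p[3])
    },
    type = "object",
    description = "Commanded stage position in motor steps (read-only; use the move action)")

  thing$add_property("frame_shape",
    getter = function() as.integer(scope$camera$frame_shape),
    type = "array", description = "Camera frame (height, width) in px")

  thing$add_property("jpeg_quality",
    getter = function() scope$camera$jpeg_quality,
    type = "integer",
    description = "Fixed JPEG quality used for all frames (bit-rate control disabled)")

  thing$add_action("move",
    func = function(args, ctx) {
      from <- scope$position()
      to <- c(args$x %||% from[1], args$y %||% from[2], args$z %||% from[3])
      n_chunk <- 6L
      for (k in seq_len(n_chunk)) {
        ctx$checkpoint()
        scope$move_to(round(from + (to - from) * k / n_chunk),
                      holder = "move")
        ctx$progress(k / n_chunk)
      }
      p <- scope$position()
      list(x = p[1], y = p[2], z = p[3])
    },
    input = list(x = "integer", y = "integer", z = "integer"),
    locks = "stage",
    description = "Move the stage to absolute (x, y, z) in motor steps")

  thing$add_action("capture",
    func = function(args, ctx) {
      ctx$checkpoint()
      rec <- capture_image(scope, store,
                           user_metadata = args$metadata %||% list())
      list(id = rec$id, href = paste0("/captures/", rec$id),
           file = basename(rec$file_path))
    },
    input = list(metadata = "object"),
    locks = "camera",
    description = "Capture a JPEG with metadata embedded in EXIF UserComment")

  if ("autofocus" %in% extensions) {
    thing$register_extension("autofocus", actions = list(
      autofocus_coarse = list(
        func = function(args, ctx) {
          af <- coarse_autofocus(scope, args$z_min, args$z_max,
                                 args$n_planes %||% 11, ctx = ctx)
          unclass(af)
        },
        input = list(z_min = "integer", z_max = "integer",
                     n_planes = "integer"),
        locks = c("stage", "camera"),
        description = "Laplacian-sharpness z-stack autofocus"),
      autofocus_fast = list(
        func = function(args, ctx) {
          af <- fast_autofocus(scope, args$z_range,
                               step = args$step %||% 10, ctx = ctx)
          unclass(af)
        },
        input = list(z_range = "integer", step = "integer"),
        locks = c("stage", "camera"),
        description = "JPEG-frame-size sweep autofocus")))
  }

  if ("calibration" %in% extensions) {
    thing$register_extension("calibration",
      actions = list(
        calibrate_camera_stage = list(
          func = function(args, ctx) {
            cal <- calibrate_camera_stage(scope, ctx = ctx)
            calibration_json(cal)
          },
          input = list(),
          locks = c("stage", "camera"),
          description = "Estimate the 2x2 px/step affine and per-axis backlash")),
      properties = list(
        camera_stage_mapping = list(
          getter = function() {
            if (is.null(scope$calibration)) NULL
            else calibration_json(scope$calibration)
          },
          type = "object",
          description = "Camera-stage calibration (null until calibrated)")))
  }

  if ("scan" %in% extensions) {
    thing$register_extension("scan", actions = list(
      tile_scan = list(
        func = function(args, ctx) {
          plan <- generate_scan_path(args$nx, args$ny,
                                     c(args$sx, args$sy),
                                     order = args$order %||% "snake",
                                     autofocus = args$autofocus %||% "none")
          summary <- run_tile_scan(scope, store, plan,
                                   use_closed_loop =
                                     args$use_closed_loop %||%
                                       !is.null(scope$calibration),
                                   ctx = ctx)
          if (summary$state == "cancelled")
            stop(vs_error("vs_cancelled", "scan aborted"))
          list(scan_id = summary$scan_id,
               sites_total = summary$sites_total,
               sites_completed = summary$sites_completed,
               state = summary$state, closed_loop = summary$closed_loop,
               captures = vapply(summary$records, function(r) r$id,
                                 character(1)))
        },
        input = list(nx = "integer", ny = "integer", sx = "integer",
                     sy = "integer", order = "string", autofocus = "string",
                     use_closed_loop = "boolean"),
        locks = c("stage", "camera"),
        description = "Tiled scan over a grid of fields of view (abortable)"),
      zstack = list(
        func = function(args, ctx) {
          recs <- acquire_zstack(scope, store, as.numeric(args$z_list),
                                 ctx = ctx)
          list(captures = vapply(recs, function(r) r$id, character(1)))
        },
        input = list(z_list = "array"),
        locks = c("stage", "camera"),
        description = "Capture one image per z plane, then restore z")))
  }

  thing
}

calibration_json <- function(cal) {
  list(A_rows = list(as.numeric(cal$A[1, ]), as.numeric(cal$A[2, ])),
       backlash_steps = as.numeric(cal$backlash_est),
       residual_rms_px = cal$residual_rms,
       timestamp = cal$timestamp)
}
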