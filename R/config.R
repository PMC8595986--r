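#' Load a server configuration file
#'
#' YAML (a flat `key: value` file is valid YAML) with these documented
#' keys, all optional:
#'
#' * `host`, `port` — server bind address (defaults 127.0.0.1, 9393)
#' * `sample`: `density`, `seed`, `shape` (height, width)
#' * `stage`: `backlash` (bx, by, bz steps), `jitter_sigma` (steps),
#'   `true_affine_rows` (two rows of the hidden px/step matrix)
#' * `camera`: `frame_shape`, `shutter_speed`, `vignette_alpha`,
#'   `blur_per_step`, `focal_radius`, `jpeg_quality`, `z_focus`
#' * `capture_root` — capture store directory
#' * `extensions` — default extensions to enable
#' * `announce_mdns` — accepted for compatibility; ignored
#'
#' @param path YAML file path.
#' @return Configuration list with defaults filled in.
#' @export
load_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg$host <- cfg$host %||% "127.0.0.1"
  cfg$port <- cfg$port %||% 9393L
  cfg$sample <- utils::modifyList(
    list(density = 0.8, seed = 1L, shape = c(1024L, 1024L)),
    cfg$sample %||% list())
  cfg$stage <- utils::modifyList(
    list(backlash = c(0, 0, 0), jitter_sigma = 0,
         true_affine_rows = list(c(1, 0), c(0, 1))),
    cfg$stage %||% list())
  cfg$camera <- utils::modifyList(
    list(frame_shape = c(120L, 160L), shutter_speed = 17,
         vignette_alpha = 0, blur_per_step = 0.05, focal_radius = Inf,
         jpeg_quality = 75L, z_focus = 500),
    cfg$camera %||% list())
  cfg$extensions <- cfg$extensions %||% c("autofocus", "calibration", "scan")
  cfg
}

#' Build a virtual microscope from a configuration
#'
#' @param cfg A list from [load_config()].
#' @return A [VirtualMicroscope].
#' @export
scope_from_config <- function(cfg) {
  A <- rbind(as.numeric(cfg$stage$true_affine_rows[[1]]),
             as.numeric(cfg$stage$true_affine_rows[[2]]))
  VirtualMicroscope$new(
    sample = generate_sample(cfg$sample$seed, cfg$sample$density,
                             cfg$sample$shape),
    stage = VirtualStage$new(backlash = as.numeric(cfg$stage$backlash),
                             jitter_sigma = cfg$stage$jitter_sigma,
                             true_affine = A, seed = cfg$sample$seed),
    camera = VirtualCamera$new(
      frame_shape = cfg$camera$frame_shape,
      shutter_speed = cfg$camera$shutter_speed,
      vignette_alpha = cfg$camera$vignette_alpha,
      blur_per_step = cfg$camera$blur_per_step,
      focal_radius = cfg$camera$focal_radius,
      jpeg_quality = cfg$camera$jpeg_quality,
      z_focus = cfg$camera$z_focus))
}
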