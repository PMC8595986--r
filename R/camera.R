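#' Virtual camera
#'
#' Renders frames from a [VirtualStage] position and a synthetic sample,
#' applying the optical imperfections of a low-cost microscope camera:
#'
#' * **Sphere-cap focal surface**: lateral stage motion carries the sample
#'   over a spherical cap, so the in-focus z depends on field position. To
#'   first order the focus offset is parabolic:
#'   `z_defocus = z_actual - z_focus - r_px^2 / (2 * focal_radius * step_scale)`
#'   with `r_px` the lateral offset of the field centre in camera pixels and
#'   `step_scale = sqrt(|det(true_affine)|)` px/step.
#' * **Defocus blur**: Gaussian blur with sigma `blur_per_step * |z_defocus|`
#'   pixels (rendered with a margin so blur has no edge artefacts).
#' * **Vignetting**: radial gain `V(r) = 1 - vignette_alpha * (r / r_max)^2`,
#'   `r_max` the centre-to-corner distance.
#' * **Exposure**: linear gain `shutter_speed / 17` ms (17 ms is the nominal
#'   exposure), clipped to `[0, 1]`.
#'
#' Every frame is encoded as baseline JPEG at one fixed `jpeg_quality`,
#' emulating a stream with bit-rate control disabled so that the encoded
#' byte size is a usable focus metric.
#' @export
VirtualCamera <- R6::R6Class("VirtualCamera",
  public = list(
    #' @field shutter_speed Exposure time, milliseconds.
    shutter_speed = 17,
    #' @field frame_shape `(height, width)` of rendered frames, px.
    frame_shape = NULL,
    #' @field vignette_alpha Radial falloff coefficient in `[0, 1)`.
    vignette_alpha = 0,
    #' @field blur_per_step Gaussian sigma in px per step of defocus.
    blur_per_step = 0.05,
    #' @field focal_radius Sphere-cap radius, steps (`Inf` = flat field).
    focal_radius = Inf,
    #' @field jpeg_quality Fixed JPEG quantisation setting (1-100).
    jpeg_quality = 75,
    #' @field z_focus In-focus z at the field centre, steps.
    z_focus = 500,

    #' @description Create a camera.
    #' @param frame_shape `(height, width)` px.
    #' @param shutter_speed ms.
    #' @param vignette_alpha in `[0, 1)`.
    #' @param blur_per_step px per step.
    #' @param focal_radius steps.
    #' @param jpeg_quality 1-100.
    #' @param z_focus steps.
    initialize = function(frame_shape = c(120, 160), shutter_speed = 17,
                          vignette_alpha = 0, blur_per_step = 0.05,
                          focal_radius = Inf, jpeg_quality = 75,
                          z_focus = 500) {
      stopifnot(length(frame_shape) == 2, all(frame_shape >= 16),
                vignette_alpha >= 0, vignette_alpha < 1,
                blur_per_step >= 0, focal_radius > 0,
                jpeg_quality >= 1, jpeg_quality <= 100)
      self$frame_shape <- as.integer(frame_shape)
      self$shutter_speed <- shutter_speed
      self$vignette_alpha <- vignette_alpha
      self$blur_per_step <- blur_per_step
      self$focal_radius <- focal_radius
      self$jpeg_quality <- as.integer(jpeg_quality)
      self$z_focus <- z_focus
    }
  )
)

#' Render a camera frame
#'
#' Crops the sample at the stage's effective position mapped through the
#' hidden ground-truth affine, applies defocus blur, vignetting and exposure
#' gain, and encodes the result as baseline JPEG at the camera's fixed
#' quality.
#'
#' Conventions: camera x is rightward (columns), y downward (rows), origin
#' top-left. Moving the stage by `+s` steps on an axis moves the imaged
#' sample content by `true_affine %*% c(s_x, s_y)` pixels on the camera.
#'
#' @param camera A [VirtualCamera].
#' @param stage A [VirtualStage].
#' @param sample A `vs_sample` from [generate_sample()].
#' @return A `vs_frame`: list with `pixels` (h x w x 3 array in `[0, 1]`),
#'   `encoded` (raw JPEG bytes), `byte_size`, `stage_snapshot` (commanded
#'   position at render time).
#' @export
render_frame <- function(camera, stage, sample) {
  act <- stage$actual()
  A <- stage$true_affine
  shp <- camera$frame_shape
  h <- shp[1]; w <- shp[2]
  sh <- dim(sample$pixels)[1]; sw <- dim(sample$pixels)[2]

  # content moves by +A.s => crop window moves by -A.s across the sample
  off <- as.numeric(A %*% act[1:2])          # (dx, dy) px, content motion
  ctr_c <- (sw + 1) / 2 - off[1]             # column = x
  ctr_r <- (sh + 1) / 2 - off[2]             # row    = y

  # defocus: parabolic sphere-cap approximation
  r_px <- sqrt(sum(off^2))
  step_scale <- sqrt(abs(det(A)))
  z_def <- act[3] - camera$z_focus -
    r_px^2 / (2 * camera$focal_radius * step_scale)
  sigma <- camera$blur_per_step * abs(z_def)

  m <- if (sigma > 0.25) as.integer(ceiling(3 * sigma)) else 0L
  if (ctr_r - (h - 1) / 2 - m < 1 || ctr_r + (h - 1) / 2 + m > sh ||
      ctr_c - (w - 1) / 2 - m < 1 || ctr_c + (w - 1) / 2 + m > sw) {
    stop("field of view (plus blur margin) outside the sample", call. = FALSE)
  }

  px <- array(0, dim = c(h + 2 * m, w + 2 * m, 3))
  for (k in 1:3) {
    px[, , k] <- bilinear_crop(sample$pixels[, , k], ctr_r, ctr_c,
                               h + 2 * m, w + 2 * m)
  }
  if (sigma > 0.25) {
    px <- EBImage::gblur(px, sigma = sigma)
    px <- px[(m + 1):(m + h), (m + 1):(m + w), , drop = FALSE]
  }

  if (camera$vignette_alpha > 0) {
    v <- vignette_profile(h, w, camera$vignette_alpha)
    for (k in 1:3) px[, , k] <- px[, , k] * v
  }

  gain <- camera$shutter_speed / 17
  px <- pmax(pmin(px * gain, 1), 0)

  enc <- encode_jpeg(px, camera$jpeg_quality)
  structure(list(pixels = px, encoded = enc, byte_size = length(enc),
                 stage_snapshot = stage$commanded()),
            class = "vs_frame")
}

#' @export
print.vs_frame <- function(x, ...) {
  cat(sprintf("<vs_frame %dx%d, %d JPEG bytes, stage (%g, %g, %g)>\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$byte_size,
              x$stage_snapshot[1], x$stage_snapshot[2], x$stage_snapshot[3]))
  invisible(x)
}

# bilinear crop of `mat` centred at real-valued (ctr_r, ctr_c), size h x w
bilinear_crop <- function(mat, ctr_r, ctr_c, h, w) {
  r <- ctr_r + seq_len(h) - (h + 1) / 2
  c <- ctr_c + seq_len(w) - (w + 1) / 2
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0;   fc <- c - c0
  nr <- nrow(mat)
  idx <- function(ri, ci) mat[cbind(rep(ri, times = w), rep(ci, each = h))]
  ri0 <- pmin(pmax(r0, 1), nr); ri1 <- pmin(r0 + 1, nr)
  ci0 <- pmin(pmax(c0, 1), ncol(mat)); ci1 <- pmin(c0 + 1, ncol(mat))
  v00 <- idx(ri0, ci0); v10 <- idx(ri1, ci0)
  v01 <- idx(ri0, ci1); v11 <- idx(ri1, ci1)
  wfr <- rep(fr, times = w); wfc <- rep(fc, each = h)
  out <- v00 * (1 - wfr) * (1 - wfc) + v10 * wfr * (1 - wfc) +
         v01 * (1 - wfr) * wfc       + v11 * wfr * wfc
  matrix(out, h, w)
}

vignette_profile <- function(h, w, alpha) {
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  r2 <- outer((seq_len(h) - cr)^2, (seq_len(w) - cc)^2, `+`)
  rmax2 <- (1 - cr)^2 + (1 - cc)^2
  1 - alpha * r2 / rmax2
}

#' Encode / decode baseline JPEG
#'
#' Thin wrappers over EBImage's JPEG I/O operating on in-memory raw vectors.
#' @param pixels h x w x 3 array in `[0, 1]`.
#' @param quality JPEG quality 1-100.
#' @return `encode_jpeg`: raw vector; `decode_jpeg`: h x w x 3 array.
#' @export
encode_jpeg <- function(pixels, quality = 75) {
  f <- tempfile(fileext = ".jpg")
  on.exit(unlink(f))
  img <- EBImage::Image(aperm(pixels, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(img, f, type = "jpeg", quality = quality)
  readBin(f, "raw", n = file.info(f)$size)
}

#' @rdname encode_jpeg
#' @param bytes Raw vector holding a JPEG stream.
#' @export
decode_jpeg <- function(bytes) {
  f <- tempfile(fileext = ".jpg")
  on.exit(unlink(f))
  writeBin(bytes, f)
  img <- EBImage::readImage(f)
  d <- dim(img)
  if (length(d) == 2) {
    px <- t(as.array(img))
    array(rep(px, 3), dim = c(dim(px), 3))
  } else {
    aperm(as.array(img)[, , 1:3], c(2, 1, 3))
  }
}
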