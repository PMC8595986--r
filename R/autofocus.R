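# Cooperative-action context: checkpoint() is the cancellation / liveness
# point; the server replaces this with one that pumps pending requests.
null_ctx <- function() {
  list(checkpoint = function() invisible(NULL),
       progress = function(frac) invisible(NULL))
}

#' Coarse z-stack autofocus
#'
#' Captures frames at `n_planes` equally spaced z positions between `z_min`
#' and `z_max`, scores each with [laplacian_sharpness()] on the greyscale
#' image, and moves the stage to the arg-max plane. Ties (within relative
#' tolerance 1e-9) are broken in favour of the first plane visited, so the
#' result is deterministic; if all planes tie the result is additionally
#' flagged `zero_contrast` (a blank field gives no focus information).
#'
#' @param scope A [VirtualMicroscope] (or any object with the same surface).
#' @param z_min,z_max Sweep range in steps, `z_min < z_max`.
#' @param n_planes Number of planes, at least 2.
#' @param ctx Internal cooperative-action context.
#' @return A `vs_autofocus` object: `best_z` (steps), `curve` (data frame of
#'   `z`, `score`), `metric_name = "laplacian"`, `method = "coarse"`,
#'   `moves_executed`, `zero_contrast`. The stage's final commanded z equals
#'   `best_z`.
#' @export
coarse_autofocus <- function(scope, z_min, z_max, n_planes = 11,
                             ctx = null_ctx()) {
  if (!(z_min < z_max)) stop("z_min must be < z_max", call. = FALSE)
  if (n_planes < 2) stop("n_planes must be at least 2", call. = FALSE)
  zs <- round(seq(z_min, z_max, length.out = n_planes))
  pos <- scope$position()
  scores <- numeric(length(zs))
  moves <- 0L
  for (i in seq_along(zs)) {
    ctx$checkpoint()
    scope$move_to(c(pos[1], pos[2], zs[i]), holder = "autofocus")
    moves <- moves + 1L
    scores[i] <- laplacian_sharpness(scope$grab_gray())
    ctx$progress(i / (length(zs) + 1))
  }
  tol <- 1e-9 * max(abs(scores), 1e-30)
  zero_contrast <- diff(range(scores)) <= tol
  best <- which(scores >= max(scores) - tol)[1]   # first visited wins ties
  scope$move_to(c(pos[1], pos[2], zs[best]), holder = "autofocus")
  moves <- moves + 1L
  ctx$progress(1)
  structure(list(best_z = zs[best],
                 curve = data.frame(z = zs, score = scores),
                 metric_name = "laplacian", method = "coarse",
                 moves_executed = moves, zero_contrast = zero_contrast),
            class = "vs_autofocus")
}

#' Fast JPEG-frame-size autofocus
#'
#' Sweeps z through `z_range` steps centred on the current position in fine
#' increments of `step`, recording the encoded JPEG byte size of each frame.
#' Because every frame is compressed at one fixed quality, byte size peaks
#' when fine detail is sharpest, i.e. at focus. The recorded curve is
#' smoothed with a centred moving average (`smooth_window` samples), the
#' peak located, and its position refined by a parabolic fit through the
#' three samples around the maximum. The stage then returns to the peak with
#' a final approach from below (consistent direction), cancelling z
#' backlash.
#'
#' If the smoothed curve is monotone over the sweep — the peak sits at
#' either end — focus lies outside the range and a `vs_focus_not_found`
#' error is raised (the stage is left at the sweep end).
#'
#' On sparse samples the byte-size metric can peak away from true focus
#' (out-of-focus blur spreads information into otherwise-empty compression
#' blocks); the metric is reliable on feature-dense samples.
#'
#' @param scope A [VirtualMicroscope].
#' @param z_range Total sweep span, steps.
#' @param step Fine step increment, steps (> 0).
#' @param smooth_window Moving-average window, samples (odd; default 5).
#' @param ctx Internal cooperative-action context.
#' @return A `vs_autofocus`: interpolated `best_z`, `curve` (data frame of
#'   `z`, `score` = bytes, `smoothed`), `metric_name = "jpeg_size"`,
#'   `method = "fast"`, `moves_executed`.
#' @export
fast_autofocus <- function(scope, z_range, step = 10, smooth_window = 5,
                           ctx = null_ctx()) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1
  pos <- scope$position()
  z0 <- pos[3] - round(z_range / 2)
  zs <- seq(z0, pos[3] + round(z_range / 2), by = step)
  if (length(zs) < max(3, smooth_window))
    stop("z_range too small for the step size", call. = FALSE)

  # approach the sweep start from below so the upward sweep is backlash-free
  scope$move_to(c(pos[1], pos[2], z0 - 5 * step), holder = "autofocus")
  sizes <- numeric(length(zs))
  moves <- 1L
  for (i in seq_along(zs)) {
    ctx$checkpoint()
    scope$move_to(c(pos[1], pos[2], zs[i]), holder = "autofocus")
    moves <- moves + 1L
    sizes[i] <- scope$grab_frame()$byte_size
    ctx$progress(i / (length(zs) + 1))
  }

  k <- rep(1 / smooth_window, smooth_window)
  sm <- as.numeric(stats::filter(sizes, k, sides = 2))
  valid <- which(!is.na(sm))
  pk <- valid[which.max(sm[valid])]
  if (pk == valid[1] || pk == valid[length(valid)]) {
    cond <- structure(
      class = c("vs_focus_not_found", "error", "condition"),
      list(message = "byte-size curve is monotone over the sweep; focus outside range",
           call = NULL))
    stop(cond)
  }

  den <- sm[pk - 1] - 2 * sm[pk] + sm[pk + 1]
  frac <- if (abs(den) < 1e-12) 0 else 0.5 * (sm[pk - 1] - sm[pk + 1]) / den
  frac <- max(-1, min(1, frac))
  best_z <- zs[pk] + frac * step

  # return to peak, approaching from below to cancel z backlash
  zi <- round(best_z)
  scope$move_to(c(pos[1], pos[2], zi - 5 * step), holder = "autofocus")
  scope$move_to(c(pos[1], pos[2], zi), holder = "autofocus")
  moves <- moves + 2L
  ctx$progress(1)
  structure(list(best_z = best_z,
                 curve = data.frame(z = zs, score = sizes, smoothed = sm),
                 metric_name = "jpeg_size", method = "fast",
                 moves_executed = moves),
            class = "vs_autofocus")
}

#' @export
print.vs_autofocus <- function(x, ...) {
  cat(sprintf("<autofocus/%s: best_z = %.1f steps, %d planes, metric %s>\n",
              x$method, x$best_z, nrow(x$curve), x$metric_name))
  invisible(x)
}
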