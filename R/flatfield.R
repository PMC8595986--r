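#' Compute a flat-field (lens shading) gain table
#'
#' From a frame of a blank, uniformly illuminated sample, estimates a coarse
#' per-channel gain grid that flattens the system's illumination response
#' (vignetting). The frame is divided into a `grid` of cells; each cell's
#' gain is `reference / local mean`, where the per-channel reference is that
#' channel's brightest cell mean — so all gains are >= 1 for a vignetted
#' uniform frame and exactly 1 where the frame is already flat.
#'
#' @param uniform_frame A `vs_frame` (or h x w x 3 array) captured on a
#'   blank (density 0) sample.
#' @param grid `(rows, cols)` of the gain grid; default `c(12, 16)`.
#' @return A `vs_flat_field`: `gains` (rows x cols x 3 array),
#'   `reference_mean` (scalar: mean over channels of the per-channel
#'   reference), `grid`, `frame_shape`.
#' @export
compute_flat_field <- function(uniform_frame, grid = c(12, 16)) {
  px <- frame_pixels(uniform_frame)
  h <- dim(px)[1]; w <- dim(px)[2]
  gr <- grid[1]; gc <- grid[2]
  stopifnot(gr >= 2, gc >= 2, h >= gr, w >= gc)
  rb <- cell_bounds(h, gr); cb <- cell_bounds(w, gc)
  gains <- array(NA_real_, dim = c(gr, gc, 3))
  refs <- numeric(3)
  for (k in 1:3) {
    cellm <- matrix(0, gr, gc)
    for (i in seq_len(gr)) for (j in seq_len(gc)) {
      cellm[i, j] <- mean(px[rb[i]:(rb[i + 1] - 1), cb[j]:(cb[j + 1] - 1), k])
    }
    if (any(cellm < 0.02)) {
      stop("degenerate input: a grid cell is near zero intensity; ",
           "cannot estimate gains", call. = FALSE)
    }
    refs[k] <- max(cellm)
    gains[, , k] <- refs[k] / cellm
  }
  structure(list(gains = gains, reference_mean = mean(refs), grid = c(gr, gc),
                 frame_shape = c(h, w)),
            class = "vs_flat_field")
}

#' Apply a flat-field gain table to a frame
#'
#' Bilinearly upsamples the coarse gain grid to the frame resolution (cell
#' centres anchor the interpolation, edges clamped), multiplies pixelwise
#' per channel, and clips to `[0, 1]`.
#'
#' @param frame A `vs_frame` or h x w x 3 pixel array.
#' @param table A `vs_flat_field` from [compute_flat_field()].
#' @return Corrected h x w x 3 pixel array.
#' @export
apply_flat_field <- function(frame, table) {
  px <- frame_pixels(frame)
  h <- dim(px)[1]; w <- dim(px)[2]
  if (h < table$grid[1] || w < table$grid[2])
    stop("frame smaller than the gain grid; cannot interpolate", call. = FALSE)
  out <- px
  for (k in 1:3) {
    g <- bilinear_upsample(table$gains[, , k], h, w)
    out[, , k] <- px[, , k] * g
  }
  pmax(pmin(out, 1), 0)
}

#' @export
print.vs_flat_field <- function(x, ...) {
  cat(sprintf("<flat field %dx%d grid, gains %.3f-%.3f, reference %.3f>\n",
              x$grid[1], x$grid[2], min(x$gains), max(x$gains),
              x$reference_mean))
  invisible(x)
}

frame_pixels <- function(x) {
  px <- if (inherits(x, "vs_frame")) x$pixels else x
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("expected a vs_frame or an h x w x 3 array", call. = FALSE)
  px
}

cell_bounds <- function(n, g) {
  # g+1 integer boundaries partitioning 1..n into g near-equal cells
  round(seq(1, n + 1, length.out = g + 1))
}

bilinear_upsample <- function(g, h, w) {
  gr <- nrow(g); gc <- ncol(g)
  # cell-centre coordinates in pixel space; linear extrapolation beyond the
  # outer centres (clamping would flatten the profile at the frame edges)
  rc <- (cell_bounds(h, gr)[-(gr + 1)] + cell_bounds(h, gr)[-1] - 1) / 2
  cc <- (cell_bounds(w, gc)[-(gc + 1)] + cell_bounds(w, gc)[-1] - 1) / 2
  ri <- 1 + (seq_len(h) - rc[1]) * (gr - 1) / (rc[gr] - rc[1])
  ci <- 1 + (seq_len(w) - cc[1]) * (gc - 1) / (cc[gc] - cc[1])
  r0 <- pmin(pmax(floor(ri), 1), gr - 1); fr <- ri - r0
  c0 <- pmin(pmax(floor(ci), 1), gc - 1); fc <- ci - c0
  v00 <- g[cbind(rep(r0, w), rep(c0, each = h))]
  v10 <- g[cbind(rep(r0 + 1, w), rep(c0, each = h))]
  v01 <- g[cbind(rep(r0, w), rep(c0 + 1, each = h))]
  v11 <- g[cbind(rep(r0 + 1, w), rep(c0 + 1, each = h))]
  wfr <- rep(fr, times = w); wfc <- rep(fc, each = h)
  matrix(v00 * (1 - wfr) * (1 - wfc) + v10 * wfr * (1 - wfc) +
         v01 * (1 - wfr) * wfc + v11 * wfr * wfc, h, w)
}
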