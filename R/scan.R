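#' Generate a tile-scan path
#'
#' Lays out an `nx` x `ny` grid of stage targets separated by `spacing`
#' steps. `"raster"` order visits every row left to right; `"snake"`
#' (boustrophedon) order reverses the x direction on alternate rows to
#' minimise travel.
#'
#' @param nx,ny Grid size, at least 1 each.
#' @param spacing `(sx, sy)` steps between adjacent sites.
#' @param order `"raster"` or `"snake"`.
#' @param autofocus Per-site autofocus: `"none"`, `"fast"` or `"coarse"`.
#' @param z_planes Optional z-stack offsets (steps) captured at every site.
#' @return A `vs_scan_plan`: data frame `sites` with columns `ix`, `iy`
#'   (grid indices from 0), `x`, `y` (step offsets from the scan origin),
#'   plus `order_name`, `spacing` and the per-site options.
#' @export
generate_scan_path <- function(nx, ny, spacing, order = c("snake", "raster"),
                               autofocus = c("none", "fast", "coarse"),
                               z_planes = NULL) {
  order <- match.arg(order)
  autofocus <- match.arg(autofocus)
  if (nx < 1 || ny < 1) stop("nx and ny must be at least 1", call. = FALSE)
  stopifnot(length(spacing) == 2)
  sites <- do.call(rbind, lapply(seq_len(ny) - 1L, function(iy) {
    ix <- seq_len(nx) - 1L
    if (order == "snake" && iy %% 2 == 1) ix <- rev(ix)
    data.frame(ix = ix, iy = iy)
  }))
  sites$x <- sites$ix * spacing[1]
  sites$y <- sites$iy * spacing[2]
  structure(list(sites = sites, order_name = order, spacing = spacing,
                 autofocus = autofocus, z_planes = z_planes),
            class = "vs_scan_plan")
}

#' @export
print.vs_scan_plan <- function(x, ...) {
  cat(sprintf("<scan plan: %d sites, %s order, spacing (%g, %g) steps>\n",
              nrow(x$sites), x$order_name, x$spacing[1], x$spacing[2]))
  invisible(x)
}

#' Acquire a z-stack
#'
#' Captures one image per z in `z_list` (monotone, non-empty), recording
#' each plane's z in the capture metadata under `user$z_plane`, then
#' returns the stage to its initial z.
#'
#' @param scope A [VirtualMicroscope].
#' @param store A [CaptureStore].
#' @param z_list Monotone vector of absolute z targets, steps.
#' @param user_metadata Extra user metadata for every capture.
#' @param ctx Internal cooperative-action context.
#' @return List of `vs_capture` records, one per plane.
#' @export
acquire_zstack <- function(scope, store, z_list, user_metadata = list(),
                           ctx = null_ctx()) {
  if (length(z_list) == 0) stop("z_list must be non-empty", call. = FALSE)
  if (length(z_list) > 1 && !(all(diff(z_list) > 0) || all(diff(z_list) < 0)))
    stop("z_list must be monotone", call. = FALSE)
  pos <- scope$position()
  recs <- vector("list", length(z_list))
  for (i in seq_along(z_list)) {
    ctx$checkpoint()
    scope$move_to(c(pos[1], pos[2], z_list[i]), holder = "zstack")
    recs[[i]] <- capture_image(scope, store,
                               c(user_metadata, list(z_plane = z_list[i])))
    ctx$progress(i / length(z_list))
  }
  scope$move_to(pos, holder = "zstack")
  recs
}

#' Run a tiled scan
#'
#' Visits every site of the plan in order. With a calibration available (and
#' `use_closed_loop = TRUE`) each inter-site move is performed closed-loop:
#' the site's target is expressed in camera pixels from the scan origin and
#' the stage is servoed onto it using image feedback, so positioning errors
#' do not accumulate over the scan. Without calibration, moves are open-loop
#' step commands. At each site the optional per-site autofocus runs, then
#' one capture (or a z-stack when the plan has `z_planes`) is written to a
#' scan sub-directory with zero-padded site indices in the filenames.
#'
#' Images are persisted incrementally: a cancellation request (via the
#' action context) takes effect at the next site boundary, every
#' already-written file remains intact, and the summary marks the scan
#' `cancelled` after the last completed site.
#'
#' @param scope A [VirtualMicroscope].
#' @param store A [CaptureStore].
#' @param plan A `vs_scan_plan`.
#' @param use_closed_loop Use image-feedback moves when calibrated.
#' @param user_metadata Extra user metadata for every capture.
#' @param ctx Internal cooperative-action context.
#' @return A `vs_scan_summary`: `scan_id`, `sites_total`,
#'   `sites_completed`, `records`, `state` (`"completed"` or
#'   `"cancelled"`), `closed_loop`.
#' @export
run_tile_scan <- function(scope, store, plan,
                          use_closed_loop = !is.null(scope$calibration),
                          user_metadata = list(), ctx = null_ctx()) {
  stopifnot(inherits(plan, "vs_scan_plan"))
  sites <- plan$sites
  n <- nrow(sites)
  scan_id <- sprintf("scan-%04d", next_scan_number())
  closed <- isTRUE(use_closed_loop) && !is.null(scope$calibration)
  origin <- scope$position()
  calib <- scope$calibration
  measured <- c(0, 0)       # cumulative measured px displacement (closed loop)
  recs <- list()
  state <- "completed"
  done <- 0L

  for (i in seq_len(n)) {
    # cancellation anywhere inside a site (move, autofocus, capture) aborts
    # cleanly at that site; files already written stay intact
    cancelled <- tryCatch({
      ctx$checkpoint()

      if (closed) {
        target_px <- as.numeric(calib$A %*% c(sites$x[i], sites$y[i]))
        res <- closed_loop_move(scope, calib, target_px - measured, ctx = ctx)
        measured <- measured + res$achieved
      } else {
        scope$move_to(c(origin[1] + sites$x[i], origin[2] + sites$y[i],
                        scope$position()[3]), holder = "scan")
      }

      if (plan$autofocus == "fast") {
        fast_autofocus(scope, z_range = 200, step = 10, ctx = ctx)
      } else if (plan$autofocus == "coarse") {
        z <- scope$position()[3]
        coarse_autofocus(scope, z - 100, z + 100, n_planes = 9, ctx = ctx)
      }

      site_meta <- c(user_metadata,
                     list(scan_id = scan_id, site = i - 1L,
                          ix = sites$ix[i], iy = sites$iy[i]))
      base <- sprintf("site-%04d", i - 1L)
      if (is.null(plan$z_planes)) {
        recs[[length(recs) + 1L]] <-
          capture_image(scope, store, site_meta, subdir = scan_id,
                        basename = base)
      } else {
        z <- scope$position()[3]
        for (j in seq_along(plan$z_planes)) {
          scope$move_to(c(scope$position()[1:2], z + plan$z_planes[j]),
                        holder = "scan")
          recs[[length(recs) + 1L]] <-
            capture_image(scope, store, c(site_meta, list(z_plane = j - 1L)),
                          subdir = scan_id,
                          basename = sprintf("%s-z%02d", base, j - 1L))
        }
        scope$move_to(c(scope$position()[1:2], z), holder = "scan")
      }
      FALSE
    }, vs_cancelled = function(e) TRUE)
    if (cancelled) { state <- "cancelled"; break }
    done <- i
    ctx$progress(i / n)
  }

  structure(list(scan_id = scan_id, sites_total = n, sites_completed = done,
                 records = recs, state = state, closed_loop = closed,
                 directory = file.path(store$root, scan_id)),
            class = "vs_scan_summary")
}

.vs_counters <- new.env(parent = emptyenv())

next_scan_number <- function() {
  n <- if (is.null(.vs_counters$scan)) 0L else .vs_counters$scan
  .vs_counters$scan <- n + 1L
  n + 1L
}

#' @export
print.vs_scan_summary <- function(x, ...) {
  cat(sprintf("<scan %s: %d/%d sites, %s%s>\n", x$scan_id,
              x$sites_completed, x$sites_total, x$state,
              if (x$closed_loop) ", closed-loop" else ""))
  invisible(x)
}
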