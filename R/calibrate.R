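#' Calibrate the camera-stage mapping and backlash
#'
#' Recovers the 2 x 2 affine matrix `A` (camera px per motor step) and the
#' per-axis mechanical backlash by moving each stage axis back and forth in
#' gradually increasing steps and measuring the resulting image displacement
#' with [measure_displacement()]. The camera's coordinate system is treated
#' as ground truth.
#'
#' Procedure, per axis:
#' 1. A take-up move in the `+` direction removes unknown initial slack
#'    (dead bands up to that move's 64 steps are supported), then a small
#'    probe move measures the axis's px-per-step magnitude so the step
#'    schedule starts at a size appropriate to the unknown magnification.
#' 2. Steps of geometrically increasing size (doubling) are commanded in
#'    the `+` direction, then the same schedule in the `-` direction (one
#'    reversal). After each move the displacement from the previous frame
#'    is measured; the schedule stops growing once the next doubling is
#'    predicted to exceed `max_frac` of the smaller frame dimension
#'    (keeping every measured shift comfortably within the reliable range
#'    of phase correlation).
#' 3. Cumulative measured displacement is projected onto the axis's motion
#'    direction and regressed on cumulative commanded position with a shared
#'    slope and separate intercepts for the `+` and `-` phases. Backlash is
#'    the intercept separation divided by the slope: motion in opposite
#'    directions is offset by exactly one dead-band width.
#' 4. The affine column is an unweighted least-squares fit of per-move
#'    displacement vectors against backlash-corrected effective steps (the
#'    first move after the reversal travels `step - backlash`).
#'
#' The stage is returned to its starting commanded position afterwards.
#'
#' @param scope A [VirtualMicroscope] with a feature-dense sample in view
#'   and in focus.
#' @param start_step Initial step size, steps (default 16).
#' @param max_frac Largest allowed image displacement per move, as a
#'   fraction of the smaller frame dimension (default 0.25).
#' @param max_doublings Cap on schedule growth (default 6).
#' @param ctx Internal cooperative-action context.
#' @return A `vs_calibration`: `A` (2 x 2, px/step), `backlash_est`
#'   `(bx, by)` steps, `residual_rms` px, `step_schedule_used`, `n_moves`.
#' @export
calibrate_camera_stage <- function(scope, start_step = 16, max_frac = 0.25,
                                   max_doublings = 6, ctx = null_ctx()) {
  pos0 <- scope$position()
  max_px <- max_frac * min(scope$camera$frame_shape)
  A <- matrix(NA_real_, 2, 2)
  backlash <- c(NA_real_, NA_real_)
  resid2 <- 0; nresid <- 0L
  schedules <- list()
  n_moves <- 0L

  for (axis in 1:2) {
    unit <- c(0, 0, 0); unit[axis] <- 1
    ctx$checkpoint()
    # take-up move: unknown initial slack is absorbed in the + direction
    scope$move_rel(round(unit * 4 * start_step), holder = "calibration")
    n_moves <- n_moves + 1L
    ref <- scope$grab_gray()

    p <- 0                      # cumulative commanded steps along the axis
    D <- c(0, 0)                # cumulative measured displacement, px
    pts <- list(list(p = 0, D = D, phase = "+", step = 0, d = c(0, 0)))
    sched <- numeric(0)

    measure_move <- function(step_signed, phase) {
      scope$move_rel(round(unit * step_signed), holder = "calibration")
      n_moves <<- n_moves + 1L
      g <- scope$grab_gray()
      d <- tryCatch(measure_displacement(ref, g), error = function(e) {
        if (inherits(e, "vs_low_confidence"))
          stop(structure(class = c("vs_calibration_failed", "error", "condition"),
                         list(message = paste("calibration aborted:", conditionMessage(e)),
                              call = NULL)))
        stop(e)
      })
      ref <<- g
      p <<- p + step_signed
      D <<- D + as.numeric(d[1:2])
      pts[[length(pts) + 1L]] <<- list(p = p, D = D, phase = phase,
                                       step = step_signed, d = as.numeric(d[1:2]))
      as.numeric(d[1:2])
    }

    # probe: 8 steps, to scale the schedule to the axis's magnification
    ctx$checkpoint()
    d8 <- measure_move(8, "+")
    pps <- sqrt(sum(d8^2)) / 8
    if (pps < 1e-4)
      stop(structure(class = c("vs_calibration_failed", "error", "condition"),
                     list(message = "no measurable motion on axis", call = NULL)))
    s <- max(4, min(4 * start_step, round(max_px / (4 * pps))))

    # + phase: grow the schedule until the next doubling is predicted to
    # exceed the allowed fraction, then pad with repeats of the final size
    # so each direction has at least 4 measured moves (keeps the fit
    # over-determined under noise)
    for (k in seq_len(max_doublings)) {
      ctx$checkpoint()
      d <- measure_move(s, "+")
      sched <- c(sched, s)
      if (2 * sqrt(sum(d^2)) > max_px) break
      s <- 2 * s
    }
    while (length(sched) < 4) {
      ctx$checkpoint()
      s2 <- sched[length(sched)]
      measure_move(s2, "+")
      sched <- c(sched, s2)
    }
    # - phase: same schedule, largest first (single reversal at the start)
    for (s2 in rev(sched)) {
      ctx$checkpoint()
      measure_move(-s2, "-")
    }
    ctx$progress(axis / 3)

    pp <- vapply(pts, `[[`, numeric(1), "p")
    DD <- t(vapply(pts, `[[`, numeric(2), "D"))
    ph <- vapply(pts, `[[`, character(1), "phase")
    u <- DD[which.max(abs(pp)), ] - DD[1, ]
    u <- u / sqrt(sum(u^2))               # axis motion direction in px space
    Du <- as.numeric(DD %*% u)
    ip <- which(ph == "+"); im <- which(ph == "-")

    # slope from the + phase alone (its slack was pre-consumed)
    fitp <- stats::lm(Du[ip] ~ pp[ip])
    slope <- stats::coef(fitp)[[2]]
    if (!is.finite(slope) || abs(slope) < 1e-6)
      stop(structure(class = c("vs_calibration_failed", "error", "condition"),
                     list(message = "singular fit: no measurable motion on axis",
                          call = NULL)))

    # endpoint first guess: commanded reversal travel minus measured travel
    i_top <- ip[length(ip)]; i_end <- length(pp)
    b0 <- max(0, (pp[i_top] - pp[i_end]) -
                   (Du[i_top] - Du[i_end]) / slope)
    # refit intercept offset using only - points past the consumption zone
    # (cumulative reversal travel beyond the estimated dead band): those lie
    # on a line parallel to the + phase, offset by slope * backlash
    cumneg <- pp[i_top] - pp[im]
    keep <- im[cumneg >= b0 + 2]
    b <- b0
    if (length(keep) >= 1) {
      xx <- pp[c(ip, keep)]; yy <- Du[c(ip, keep)]
      g <- c(rep(0, length(ip)), rep(1, length(keep)))
      fit <- stats::lm(yy ~ xx + g)
      if (is.finite(stats::coef(fit)[["g"]]) &&
          abs(stats::coef(fit)[["xx"]]) > 1e-6) {
        slope <- stats::coef(fit)[["xx"]]
        b <- abs(stats::coef(fit)[["g"]] / slope)
      }
    }
    backlash[axis] <- b

    # affine column from dead-band-corrected per-move effective steps
    steps_eff <- numeric(0); disp <- NULL
    cum <- 0
    for (q in pts[-1]) {
      if (q$phase == "+") {
        eff <- q$step
      } else {
        cprev <- cum; cum <- cum + abs(q$step)
        eff <- -(max(0, cum - b) - max(0, cprev - b))
      }
      steps_eff <- c(steps_eff, eff)
      disp <- rbind(disp, q$d)
    }
    use <- abs(steps_eff) > 1e-9
    col <- colSums(disp[use, , drop = FALSE] * steps_eff[use]) /
      sum(steps_eff[use]^2)
    A[, axis] <- col
    pred <- outer(steps_eff[use], col)
    resid2 <- resid2 + sum((disp[use, , drop = FALSE] - pred)^2)
    nresid <- nresid + sum(use)
    schedules[[axis]] <- sched

    scope$move_to(pos0, holder = "calibration")
    n_moves <- n_moves + 1L
  }

  if (abs(det(A)) < 1e-9)
    stop(structure(class = c("vs_calibration_failed", "error", "condition"),
                   list(message = "singular affine fit", call = NULL)))
  ctx$progress(1)
  cal <- structure(list(A = A, backlash_est = backlash,
                        residual_rms = sqrt(resid2 / max(1L, 2L * nresid)),
                        step_schedule_used = schedules, n_moves = n_moves,
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                   class = "vs_calibration")
  scope$calibration <- cal
  cal
}

#' @export
print.vs_calibration <- function(x, ...) {
  cat("<camera-stage calibration>\n  A (px/step):\n")
  print(round(x$A, 4))
  cat(sprintf("  backlash: (%.2f, %.2f) steps; residual RMS %.3f px\n",
              x$backlash_est[1], x$backlash_est[2], x$residual_rms))
  invisible(x)
}

#' Persist / restore a calibration as structured text
#'
#' YAML document with the matrix rows, backlash, residual and timestamp.
#' @param calib A `vs_calibration`.
#' @param path File path.
#' @export
save_calibration <- function(calib, path) {
  doc <- list(schema = "virtuscope-calibration/1",
              A_rows = list(as.numeric(calib$A[1, ]), as.numeric(calib$A[2, ])),
              backlash_steps = as.numeric(calib$backlash_est),
              residual_rms_px = calib$residual_rms,
              timestamp = calib$timestamp)
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  doc <- yaml::read_yaml(path)
  structure(list(A = rbind(doc$A_rows[[1]], doc$A_rows[[2]]),
                 backlash_est = doc$backlash_steps,
                 residual_rms = doc$residual_rms_px,
                 step_schedule_used = NULL, n_moves = NA_integer_,
                 timestamp = doc$timestamp),
            class = "vs_calibration")
}

#' Closed-loop stage translation using image feedback
#'
#' Moves the stage so the imaged sample translates by `target_px` on the
#' camera, using the calibrated affine to convert the remaining pixel error
#' into steps and re-measuring the actually achieved displacement from
#' frames after every correction. Long corrections are executed as sub-hops
#' no larger than a quarter of the smaller frame dimension so each
#' displacement measurement stays within phase correlation's reliable
#' range; measured displacement accumulates across hops.
#'
#' Iterates up to `max_iter` correction cycles or until the remaining error
#' is below `tol` px. Non-convergence raises a `vs_not_converged` error
#' carrying the best achieved displacement in its `achieved` field.
#'
#' @param scope A [VirtualMicroscope].
#' @param calib A `vs_calibration`.
#' @param target_px `(dx, dy)` target displacement of the sample content on
#'   the camera, px.
#' @param tol Convergence tolerance, px (default 1).
#' @param max_iter Maximum correction cycles (default 5).
#' @param ctx Internal cooperative-action context.
#' @return List: `achieved` (measured `(dx, dy)` px), `iterations`,
#'   `converged`.
#' @export
closed_loop_move <- function(scope, calib, target_px, tol = 1, max_iter = 5,
                             ctx = null_ctx()) {
  target_px <- as.numeric(target_px)
  stopifnot(length(target_px) == 2)
  if (all(target_px == 0))
    return(list(achieved = c(0, 0), iterations = 0L, converged = TRUE))
  max_hop <- min(scope$camera$frame_shape) / 4
  ref <- scope$grab_gray()
  measured <- c(0, 0)
  iters <- 0L
  repeat {
    err <- target_px - measured
    if (sqrt(sum(err^2)) < tol) break
    if (iters >= max_iter) {
      stop(structure(class = c("vs_not_converged", "error", "condition"),
                     list(message = sprintf(
                       "closed-loop move did not converge within %d iterations (%.2f px remaining)",
                       max_iter, sqrt(sum(err^2))),
                       call = NULL, achieved = measured)))
    }
    iters <- iters + 1L
    n_hop <- max(1L, ceiling(sqrt(sum(err^2)) / max_hop))
    for (hh in seq_len(n_hop)) {
      ctx$checkpoint()
      hop_px <- err * (hh / n_hop) - err * ((hh - 1) / n_hop)
      dstep <- solve(calib$A, hop_px)
      scope$move_rel(c(round(dstep), 0), holder = "closed_loop")
      g <- scope$grab_gray()
      d <- measure_displacement(ref, g)
      ref <- g
      measured <- measured + as.numeric(d[1:2])
    }
  }
  list(achieved = measured, iterations = iters, converged = TRUE)
}

#' Open-loop stage translation (no feedback)
#'
#' Commands `round(A^-1 target_px)` steps in one shot. Provided as the
#' baseline closed-loop translation is compared against: with backlash or
#' calibration error, open-loop positioning errors accumulate over a scan.
#'
#' @inheritParams closed_loop_move
#' @return Commanded step vector, invisibly.
#' @export
open_loop_move <- function(scope, calib, target_px) {
  dstep <- solve(calib$A, as.numeric(target_px))
  scope$move_rel(c(round(dstep), 0), holder = "open_loop")
  invisible(dstep)
}

#' Ground-truth pixel position of the stage (simulator only)
#'
#' Maps the stage's *actual* (x, y) through the hidden true affine. Tests
#' use this to score positioning error; algorithms must not call it.
#' @param scope A [VirtualMicroscope].
#' @export
true_pixel_position <- function(scope) {
  as.numeric(scope$stage$true_affine %*% scope$stage$actual()[1:2])
}
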