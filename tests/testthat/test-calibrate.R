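test_that("a perfect stage calibrates to identity with negligible backlash", {
  sc <- test_scope(density = 0.8, seed = 1, sample_shape = c(1024, 1024))
  cal <- calibrate_camera_stage(sc)
  expect_lt(max(abs(cal$A - diag(2))), 0.01)
  expect_true(all(cal$backlash_est < 0.5))
  expect_equal(sc$position(), c(0, 0, sc$camera$z_focus))  # returned to start
  expect_gte(cal$residual_rms, 0)
})

test_that("a rotated, scaled affine is recovered within 2% per element", {
  A <- matrix(c(0, 2, -2, 0), 2, 2)
  sc <- test_scope(density = 0.8, seed = 2, true_affine = A,
                   sample_shape = c(1024, 1024))
  cal <- calibrate_camera_stage(sc)
  expect_lt(max(abs(cal$A - A)) / max(abs(A)), 0.02)
})

test_that("backlash is estimated within a step under pixel-scale jitter", {
  errs <- vapply(1:5, function(seed) {
    sc <- test_scope(density = 0.8, seed = seed, backlash = c(15, 15, 0),
                     jitter_sigma = 0.5, sample_shape = c(1024, 1024))
    cal <- calibrate_camera_stage(sc)
    max(abs(cal$backlash_est - 15))
  }, numeric(1))
  expect_lte(stats::median(errs), 1)
})

test_that("backlash estimation is unbiased across dead-band widths", {
  for (b in c(0, 5, 40)) {
    sc <- test_scope(density = 0.8, seed = 20 + b, backlash = c(b, b, 0),
                     jitter_sigma = 0.5, sample_shape = c(1024, 1024))
    cal <- calibrate_camera_stage(sc)
    expect_lt(max(abs(cal$backlash_est - b)), 1.5,
              label = sprintf("backlash %d", b))
  }
})

test_that("calibration aborts with a diagnostic on a featureless sample", {
  sc <- test_scope(density = 0, seed = 1)
  expect_error_class(calibrate_camera_stage(sc), "vs_calibration_failed")
})

test_that("calibrations round-trip through the YAML document", {
  sc <- test_scope(density = 0.8, seed = 3, sample_shape = c(1024, 1024))
  cal <- calibrate_camera_stage(sc)
  f <- tempfile(fileext = ".yaml")
  save_calibration(cal, f)
  cal2 <- load_calibration(f)
  expect_equal(as.numeric(cal2$A), as.numeric(cal$A), tolerance = 1e-9)
  expect_equal(as.numeric(cal2$backlash_est), as.numeric(cal$backlash_est),
               tolerance = 1e-9)
  expect_equal(as.numeric(cal2$residual_rms), as.numeric(cal$residual_rms),
               tolerance = 1e-9)
  unlink(f)
})

test_that("closed-loop moves hit pixel targets; a zero target does nothing", {
  sc <- test_scope(density = 0.8, seed = 4, sample_shape = c(1024, 1024))
  cal <- calibrate_camera_stage(sc)

  res0 <- closed_loop_move(sc, cal, c(0, 0))
  expect_equal(res0$achieved, c(0, 0))
  expect_equal(res0$iterations, 0L)

  p0 <- true_pixel_position(sc)
  res <- closed_loop_move(sc, cal, c(120, -80))
  expect_lte(res$iterations, 2)
  expect_true(res$converged)
  expect_lt(max(abs((true_pixel_position(sc) - p0) - c(120, -80))), 1)
})

test_that("closed-loop moves converge on a backlash stage and report
           non-convergence honestly", {
  sc <- test_scope(density = 0.8, seed = 5, backlash = c(15, 15, 0),
                   sample_shape = c(1024, 1024))
  cal <- calibrate_camera_stage(sc)
  p0 <- true_pixel_position(sc)
  res <- closed_loop_move(sc, cal, c(-60, 45))
  expect_lt(max(abs((true_pixel_position(sc) - p0) - c(-60, 45))), 1.5)

  err <- expect_error_class(
    closed_loop_move(sc, cal, c(40, 0), tol = 1e-6, max_iter = 1),
    "vs_not_converged")
  expect_true(is.numeric(err$achieved))
})

test_that("affine recovery stays within 2% over random well-conditioned affines", {
  set.seed(77)
  rel_errs <- c()
  for (k in 1:6) {
    repeat {
      A <- matrix(stats::runif(4, -2, 2), 2, 2)
      if (abs(det(A)) > 0.3 && kappa(A) < 10) break
    }
    pps <- sqrt(abs(det(A)))
    sc <- test_scope(density = 0.8, seed = 30 + k, true_affine = A,
                     jitter_sigma = 0.5 / pps, sample_shape = c(1024, 1024))
    cal <- calibrate_camera_stage(sc)
    rel_errs <- c(rel_errs, abs(cal$A - A) / max(abs(A)))
  }
  expect_lt(stats::median(rel_errs), 0.02)
})
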