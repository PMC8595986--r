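test_that("captures embed a metadata document that round-trips from disk", {
  sc <- test_scope(seed = 1)
  store <- CaptureStore$new(tempfile("store-"))
  sc$move_to(c(12, -7, 500))
  rec <- capture_image(sc, store, user_metadata = list(sample = "toy"))
  expect_true(file.exists(rec$file_path))

  meta <- read_capture_metadata(rec$file_path)
  expect_equal(meta$schema, "virtuscope/1")
  expect_equal(meta$stage$position$x, 12)
  expect_equal(meta$stage$position$y, -7)
  expect_equal(meta$stage$position$z, 500)
  expect_equal(meta$user$sample, "toy")
  expect_equal(meta$camera$shutter_speed_ms, 17)

  rec2 <- capture_image(sc, store)
  expect_false(rec$id == rec2$id)
  expect_false(rec$file_path == rec2$file_path)
  # the index matches the files on disk exactly
  on_disk <- sort(list.files(store$root, recursive = TRUE, full.names = TRUE))
  indexed <- sort(unname(vapply(store$list(), function(r) r$file_path,
                                character(1))))
  expect_equal(indexed, on_disk)
})

test_that("capture metadata includes the calibration snapshot when present", {
  sc <- test_scope(density = 0.8, seed = 2, sample_shape = c(1024, 1024))
  store <- CaptureStore$new(tempfile("store-"))
  calibrate_camera_stage(sc)
  rec <- capture_image(sc, store)
  meta <- read_capture_metadata(rec$file_path)
  expect_equal(unlist(meta$calibration$A_rows[1,]), c(1, 0), tolerance = 0.02)
  expect_length(meta$calibration$backlash_steps, 2)
})

test_that("scan paths follow the raster and snake definitions exactly", {
  sn <- generate_scan_path(2, 2, c(40, 40), order = "snake")
  expect_equal(sn$sites$ix, c(0, 1, 1, 0))
  expect_equal(sn$sites$iy, c(0, 0, 1, 1))

  ra <- generate_scan_path(2, 2, c(40, 40), order = "raster")
  expect_equal(ra$sites$ix, c(0, 1, 0, 1))
  expect_equal(ra$sites$iy, c(0, 0, 1, 1))

  one <- generate_scan_path(1, 1, c(10, 10))
  expect_equal(nrow(one$sites), 1L)
  # consecutive sites always differ
  d <- diff(as.matrix(sn$sites[, c("ix", "iy")]))
  expect_true(all(rowSums(abs(d)) > 0))

  expect_error(generate_scan_path(2, 2, c(1, 1), order = "spiral"))
  expect_error(generate_scan_path(0, 2, c(1, 1)), "at least 1")
})

test_that("z-stacks record each plane and restore the starting height", {
  sc <- test_scope(seed = 3)
  store <- CaptureStore$new(tempfile("store-"))
  sc$move_to(c(0, 0, 480))
  recs <- acquire_zstack(sc, store, c(460, 500, 540))
  expect_length(recs, 3)
  zs <- vapply(recs, function(r)
    read_capture_metadata(r$file_path)$user$z_plane, numeric(1))
  expect_equal(zs, c(460, 500, 540))
  expect_equal(sc$position()[3], 480)

  expect_error(acquire_zstack(sc, store, numeric(0)), "non-empty")
  expect_error(acquire_zstack(sc, store, c(1, 3, 2)), "monotone")
})

test_that("a full tile scan captures every site with adjacency consistent
           with the calibration", {
  sc <- test_scope(density = 0.8, seed = 4, sample_shape = c(1024, 1024))
  store <- CaptureStore$new(tempfile("store-"))
  cal <- calibrate_camera_stage(sc)
  plan <- generate_scan_path(3, 3, c(30, 30), order = "snake")
  summary <- run_tile_scan(sc, store, plan)
  expect_equal(summary$state, "completed")
  expect_equal(summary$sites_completed, 9L)
  expect_length(summary$records, 9)
  files <- list.files(summary$directory, pattern = "site-\\d{4}\\.jpg")
  expect_length(files, 9)

  # adjacency: consecutive tiles are displaced by A * (commanded step)
  g1 <- to_grayscale(decode_jpeg(readBin(summary$records[[1]]$file_path, "raw",
    n = file.info(summary$records[[1]]$file_path)$size)))
  g2 <- to_grayscale(decode_jpeg(readBin(summary$records[[2]]$file_path, "raw",
    n = file.info(summary$records[[2]]$file_path)$size)))
  d <- measure_displacement(g1, g2)
  expect_lt(max(abs(d - as.numeric(cal$A %*% c(30, 0)))), 2)
})

test_that("aborting a scan preserves exactly the completed sites", {
  sc <- test_scope(density = 0.8, seed = 5, sample_shape = c(1024, 1024))
  store <- CaptureStore$new(tempfile("store-"))
  plan <- generate_scan_path(3, 3, c(30, 30))
  # cancel at the 5th site boundary: sites run one checkpoint each here
  # (open loop, no autofocus), so 4 sites complete
  summary <- run_tile_scan(sc, store, plan, use_closed_loop = FALSE,
                           ctx = cancelling_ctx(after = 4))
  expect_equal(summary$state, "cancelled")
  expect_equal(summary$sites_completed, 4L)
  files <- list.files(summary$directory, full.names = TRUE)
  expect_length(files, 4)
  for (f in files) {
    px <- decode_jpeg(readBin(f, "raw", n = file.info(f)$size))  # all intact
    expect_equal(dim(px)[3], 3)
    expect_false(is.null(read_capture_metadata(f)))
  }
})
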