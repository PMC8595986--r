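# End-to-end tests over real TCP: the server runs in a forked child
# process, the test process acts as the client.

start_test_server <- function(port, density = 0.8, seed = 2,
                              sample_shape = c(1024, 1024)) {
  job <- parallel::mcparallel({
    sc <- virtual_microscope(density = density, seed = seed,
                             sample_shape = sample_shape)
    sc$move_to(c(0, 0, sc$camera$z_focus))
    thing <- build_microscope_thing(sc, CaptureStore$new(tempfile("store-")))
    run_server(thing, port = port, log_con = file(nullfile(), "w"))
  })
  # wait for the socket to come up
  up <- FALSE
  for (i in 1:50) {
    r <- tryCatch(
      suppressWarnings(http_request("127.0.0.1", port, "GET", "/td",
                                    timeout = 2)),
      error = function(e) NULL)
    if (!is.null(r) && r$status == 200) { up <- TRUE; break }
    Sys.sleep(0.2)
  }
  if (!up) {
    tools::pskill(job$pid)
    stop("test server did not come up on port ", port)
  }
  job
}

stop_test_server <- function(job) {
  tools::pskill(job$pid)
  parallel::mccollect(job, wait = FALSE)
  invisible(NULL)
}

test_that("the shutter-speed property round-trips over real HTTP", {
  port <- 20000L + (Sys.getpid() %% 10000L)
  job <- start_test_server(port)
  on.exit(stop_test_server(job))

  r <- http_request("127.0.0.1", port, "GET", "/properties/shutter_speed")
  expect_equal(r$status, 200L)
  expect_equal(r$json, 17)

  r2 <- http_request("127.0.0.1", port, "PUT", "/properties/shutter_speed",
                     "22")
  expect_equal(r2$status, 200L)
  r3 <- http_request("127.0.0.1", port, "GET", "/properties/shutter_speed")
  expect_equal(r3$json, 22)

  # the proxy over the same wire behaves identically
  proxy <- connect(sprintf("http://127.0.0.1:%d", port))
  expect_equal(proxy$get_property("shutter_speed"), 22)
  out <- proxy$actions$move(x = 25, y = -10, z = 500)
  expect_equal(c(out$x, out$y), c(25, -10))
  pos <- proxy$get_property("stage_position")
  expect_equal(c(pos$x, pos$y), c(25, -10))
})

test_that("a conflicting move is denied 409 while an autofocus holds the
           stage over HTTP, and the first action completes", {
  port <- 21000L + (Sys.getpid() %% 10000L)
  job <- start_test_server(port)
  on.exit(stop_test_server(job))
  proxy <- connect(sprintf("http://127.0.0.1:%d", port))

  rec <- proxy$actions$autofocus_fast(z_range = 400, step = 10,
                                      .blocking = FALSE)
  expect_true(rec$state %in% c("pending", "running"))
  Sys.sleep(0.5)                      # let the sweep begin
  err <- expect_error_class(proxy$actions$move(x = 1, y = 0, z = 500),
                            "vs_busy")
  expect_match(conditionMessage(err), "stage")

  # the autofocus is unaffected and completes with a sensible focus
  wait <- 0.2; deadline <- Sys.time() + 60
  repeat {
    pr <- http_request("127.0.0.1", port, "GET", rec$href)
    if (pr$json$state %in% c("completed", "error", "cancelled")) break
    if (Sys.time() > deadline) stop("autofocus never finished")
    Sys.sleep(wait); wait <- min(1, wait * 1.5)
  }
  expect_equal(pr$json$state, "completed")
  expect_lt(abs(pr$json$output$best_z - 500), 20)
})

test_that("the MJPEG stream delivers strictly increasing frame indices over
           TCP", {
  port <- 22000L + (Sys.getpid() %% 10000L)
  job <- start_test_server(port)
  on.exit(stop_test_server(job))

  con <- socketConnection("127.0.0.1", port, blocking = TRUE, open = "a+b",
                          timeout = 10)
  writeBin(charToRaw("GET /stream HTTP/1.1\r\nHost: t\r\n\r\n"), con)
  buf <- raw(0); t0 <- Sys.time()
  while (length(buf) < 15000 && as.numeric(Sys.time() - t0) < 30) {
    ch <- readBin(con, "raw", n = 8192)
    if (length(ch)) buf <- c(buf, ch)
  }
  close(con)
  # parse X-Frame-Index headers out of the raw multipart bytes
  pat <- charToRaw("X-Frame-Index: ")
  idx <- integer(0)
  i <- 1
  while (i + length(pat) < length(buf)) {
    if (identical(buf[i:(i + length(pat) - 1)], pat)) {
      j <- i + length(pat)
      digits <- c()
      while (buf[j] >= as.raw(48) && buf[j] <= as.raw(57)) {
        digits <- c(digits, buf[j]); j <- j + 1
      }
      idx <- c(idx, as.integer(rawToChar(as.raw(digits))))
      i <- j
    } else i <- i + 1
  }
  expect_gte(length(idx), 2)
  expect_true(all(diff(idx) > 0))     # no duplicates, in order
})
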