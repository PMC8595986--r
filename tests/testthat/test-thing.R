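make_thing <- function(...) {
  sc <- test_scope(density = 0.8, seed = 1, ...)
  build_microscope_thing(sc, CaptureStore$new(tempfile("store-")))
}

test_that("property reads and writes follow the HTTP contract", {
  thing <- make_thing()
  r <- thing$handle("GET", "/properties/shutter_speed")
  expect_equal(r$status, 200L)
  expect_equal(r$json, 17)

  r <- thing$handle("PUT", "/properties/shutter_speed", "22")
  expect_equal(r$status, 200L)
  expect_equal(thing$handle("GET", "/properties/shutter_speed")$json, 22)

  expect_equal(thing$handle("GET", "/properties/nope")$status, 404L)
  expect_equal(thing$handle("PUT", "/properties/stage_position",
                            "{\"x\":1}")$status, 405L)
  expect_equal(thing$handle("PUT", "/properties/shutter_speed",
                            "\"fast\"")$status, 400L)
  expect_equal(thing$handle("PUT", "/properties/shutter_speed",
                            "-3")$status, 400L)

  pos <- thing$handle("GET", "/properties/stage_position")
  expect_equal(pos$status, 200L)
  expect_equal(pos$json$z, 500)
})

test_that("action invocation is asynchronous: 201 with a pollable record", {
  thing <- make_thing()
  r <- thing$handle("POST", "/actions/move", "{\"x\":40,\"y\":0,\"z\":500}")
  expect_equal(r$status, 201L)
  expect_true(r$json$state %in% c("pending", "running"))
  expect_match(r$json$href, "^/action-records/")
  expect_equal(r$headers$Location, r$json$href)

  thing$run_pending()
  polled <- thing$handle("GET", r$json$href)
  expect_equal(polled$json$state, "completed")
  expect_equal(polled$json$output$x, 40)
  expect_equal(polled$json$progress, 1)

  expect_equal(thing$handle("POST", "/actions/teleport", "{}")$status, 404L)
  expect_equal(thing$handle("POST", "/actions/move",
                            "{\"warp\":1}")$status, 400L)
})

test_that("cancellation follows the record state machine", {
  thing <- make_thing()
  rec <- thing$invoke("move", list(x = 10, y = 0, z = 500))
  # pending records cancel before they start
  expect_equal(thing$handle("DELETE", rec$href)$json$state, "cancelled")
  thing$run_pending()
  expect_equal(thing$record(rec$id)$state, "cancelled")

  # terminal records refuse cancellation
  rec2 <- thing$invoke("move", list(x = 20, y = 0, z = 500))
  thing$run_pending()
  expect_equal(thing$handle("DELETE", rec2$href)$status, 409L)
  expect_equal(thing$handle("DELETE", "/action-records/act-zzz")$status, 404L)
})

test_that("record states only move along the declared edges under random
           invoke/cancel/poll sequences", {
  thing <- make_thing()
  rank <- c(pending = 0, running = 1, completed = 2, cancelled = 2, error = 2)
  seen <- new.env(parent = emptyenv())
  observe <- function() {
    for (id in thing$record_ids()) {
      st <- thing$record(id)$state
      prev <- seen[[id]]
      if (!is.null(prev)) {
        expect_gte(rank[[st]], rank[[prev]])
        if (rank[[prev]] == 2) expect_identical(st, prev)
      }
      seen[[id]] <- st
    }
  }
  set.seed(21)
  for (k in 1:40) {
    op <- sample(c("invoke", "cancel", "run", "poll"), 1)
    if (op == "invoke") {
      thing$invoke("move", list(x = sample(-50:50, 1), y = 0, z = 500))
    } else if (op == "cancel" && length(thing$record_ids())) {
      thing$cancel(sample(thing$record_ids(), 1))
    } else if (op == "run") {
      thing$run_pending()
    }
    observe()
  }
})

test_that("hardware locks serialize actions: conflicting moves are denied 409
           while reads stay live", {
  thing <- make_thing(sample_shape = c(1024, 1024))
  rec <- thing$invoke("tile_scan", list(nx = 2, ny = 2, sx = 30, sy = 30))
  thing$enqueue_request("read", "GET", "/properties/shutter_speed")
  thing$enqueue_request("move", "POST", "/actions/move",
                        "{\"x\":0,\"y\":0,\"z\":500}")
  thing$run_record(rec$id)

  read_resp <- thing$queued_response("read")
  expect_equal(read_resp$status, 200L)          # answered mid-scan
  expect_equal(read_resp$json, 17)

  move_resp <- thing$queued_response("move")
  expect_equal(move_resp$status, 409L)
  expect_equal(move_resp$json$lock, "stage")    # names the held lock
  expect_equal(thing$record(rec$id)$state, "completed")

  # the denied move never issued a hardware command during the scan
  holders <- vapply(thing$scope$stage$command_log, function(e) e$holder,
                    character(1))
  expect_false("move" %in% holders)
})

test_that("re-entrant locks admit their holder and refuse others", {
  lr <- LockRegistry$new()
  expect_true(lr$acquire("stage", "a"))
  expect_true(lr$acquire("stage", "a"))      # re-entrant
  expect_false(lr$acquire("stage", "b"))
  lr$release("stage", "a")
  expect_false(lr$acquire("stage", "b"))     # still held once
  lr$release("stage", "a")
  expect_true(lr$acquire("stage", "b"))
  lr$release_all("b")
  expect_null(lr$holder_of("stage"))
})

test_that("the Thing Description enumerates exactly the registered affordances
           and is stable", {
  thing <- make_thing()
  td <- thing_description(thing)
  expect_setequal(names(td$properties), names(thing$properties()))
  expect_setequal(names(td$actions), names(thing$actions()))
  expect_true(all(c("shutter_speed", "stage_position") %in%
                    names(td$properties)))
  expect_true(all(c("move", "capture", "autofocus_coarse", "autofocus_fast",
                    "tile_scan") %in% names(td$actions)))
  expect_identical(to_json_body(td), to_json_body(thing_description(thing)))

  # read-only properties advertise no writeproperty op
  ops <- unlist(td$properties$stage_position$forms[[1]]$op)
  expect_false("writeproperty" %in% ops)
})

test_that("extensions register, extend the TD, refuse duplicates, and can be
           disabled at boot", {
  thing <- make_thing()
  thing$register_extension("demo", actions = list(
    blink = list(func = function(args, ctx) list(ok = TRUE),
                 description = "demo action")))
  td <- thing_description(thing)
  expect_true("blink" %in% names(td$actions))
  expect_equal(td$actions$blink$forms[[1]]$href,
               "/extensions/demo/actions/blink")

  r <- thing$handle("POST", "/extensions/demo/actions/blink", "{}")
  expect_equal(r$status, 201L)
  thing$run_pending()
  expect_true(thing$record(r$json$id)$output$ok)

  expect_error(thing$register_extension("demo"), "already registered")

  bare <- build_microscope_thing(test_scope(seed = 1),
                                 CaptureStore$new(tempfile("store-")),
                                 extensions = character(0))
  td2 <- thing_description(bare)
  expect_false("autofocus_fast" %in% names(td2$actions))
  expect_false("camera_stage_mapping" %in% names(td2$properties))
})

test_that("every URL advertised in the TD answers a request (crawl)", {
  thing <- make_thing()
  thing$register_extension("demo", actions = list(
    blink = list(func = function(args, ctx) list(ok = TRUE))))
  td <- thing_description(thing)
  hrefs <- c(
    vapply(td$properties, function(p) p$forms[[1]]$href, character(1)),
    vapply(td$actions, function(a) a$forms[[1]]$href, character(1)),
    "/", "/td", "/openapi.json", "/properties", "/actions",
    "/action-records", "/captures", "/stream")
  for (h in hrefs) {
    expect_false(thing$handle("GET", h)$status == 404L, label = h)
  }
})

test_that("the OpenAPI document is structurally valid and agrees with the TD", {
  thing <- make_thing()
  oa <- openapi_description(thing)
  expect_match(oa$openapi, "^3\\.0\\.")
  expect_true(is.character(oa$info$title) && is.character(oa$info$version))
  expect_gt(length(oa$paths),
            length(thing$properties()) + length(thing$actions()))
  for (p in names(oa$paths)) {
    methods <- oa$paths[[p]]
    expect_true(all(names(methods) %in% c("get", "put", "post", "delete")),
                label = p)
    for (m in methods) {
      expect_true(is.character(m$summary))
      expect_gt(length(m$responses), 0)
    }
  }
  td <- thing_description(thing)
  forms <- c(vapply(td$properties, function(p) p$forms[[1]]$href, character(1)),
             vapply(td$actions, function(a) a$forms[[1]]$href, character(1)))
  expect_true(all(forms %in% names(oa$paths)))
})

test_that("terminal action records are garbage-collected beyond the retention
           capacity", {
  thing <- make_thing()
  thing$record_retention <- 5L
  for (k in 1:8) {
    thing$invoke("move", list(x = k, y = 0, z = 500))
    thing$run_pending()
  }
  expect_lte(length(thing$record_ids()), 6L)
})
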