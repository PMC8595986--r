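#' Registry of named re-entrant hardware locks
#'
#' One lock per hardware unit (stage, camera). A lock is held by at most one
#' holder (action record id) at a time; re-entrant acquisition by the
#' current holder always succeeds and must be released as many times as
#' acquired.
#' @export
LockRegistry <- R6::R6Class("LockRegistry",
  public = list(
    #' @description Try to acquire `name` for `holder`.
    #' @param name Lock name.
    #' @param holder Holder token.
    #' @return `TRUE` on success, `FALSE` if held by another holder.
    acquire = function(name, holder) {
      l <- private$locks[[name]]
      if (is.null(l) || l$count == 0L || identical(l$holder, holder)) {
        if (is.null(l) || l$count == 0L) l <- list(holder = holder, count = 0L)
        l$count <- l$count + 1L
        private$locks[[name]] <- l
        TRUE
      } else FALSE
    },
    #' @description Release one acquisition of `name` by `holder`.
    #' @param name Lock name.
    #' @param holder Holder token.
    release = function(name, holder) {
      l <- private$locks[[name]]
      if (is.null(l) || l$count == 0L || !identical(l$holder, holder))
        return(invisible(FALSE))
      l$count <- l$count - 1L
      private$locks[[name]] <- l
      invisible(TRUE)
    },
    #' @description Release everything `holder` holds.
    #' @param holder Holder token.
    release_all = function(holder) {
      for (nm in names(private$locks)) {
        l <- private$locks[[nm]]
        if (identical(l$holder, holder)) l$count <- 0L
        private$locks[[nm]] <- l
      }
      invisible(TRUE)
    },
    #' @description Current holder of `name`, or `NULL` if free.
    #' @param name Lock name.
    holder_of = function(name) {
      l <- private$locks[[name]]
      if (is.null(l) || l$count == 0L) NULL else l$holder
    }
  ),
  private = list(locks = list())
)

#' Web-of-Things device core
#'
#' Represents the microscope (or any instrument) as a set of *interaction
#' affordances* — properties (read / read-write values) and actions
#' (possibly long-running operations) — addressable over an HTTP-style
#' request interface, plus the machinery around them: background action
#' records with lifecycle states, re-entrant hardware locks, a frame buffer
#' feeding MJPEG stream clients, an extension mechanism, and generated
#' Thing Description and OpenAPI documents.
#'
#' Concurrency model: actions run cooperatively. An invocation immediately
#' returns a `pending` action record (HTTP 201 with the record and its
#' pollable `href`); the record is executed by [Thing]`$run_pending()` —
#' called by the HTTP server loop or the local client transport — and the
#' running action yields at *checkpoints*, where the Thing pumps queued
#' requests (property reads, cancellations, stream frames) and honours
#' cancellation. Hardware conflicts are refused at invocation time with
#' status 409 naming the held lock. The observable contract matches a
#' threaded server: reads stay live during long actions, conflicting moves
#' are denied, scans abort cleanly at site boundaries.
#' @export
Thing <- R6::R6Class("Thing",
  public = list(
    #' @field title Device title (appears in the Thing Description).
    title = NULL,
    #' @field scope The instrument (a [VirtualMicroscope]) or `NULL`.
    scope = NULL,
    #' @field store The [CaptureStore] or `NULL`.
    store = NULL,
    #' @field locks The [LockRegistry].
    locks = NULL,
    #' @field record_retention Terminal action records kept before GC.
    record_retention = 100L,

    #' @description Create a Thing.
    #' @param title Device title.
    #' @param scope Optional instrument object.
    #' @param store Optional capture store.
    initialize = function(title = "virtuscope", scope = NULL, store = NULL) {
      self$title <- title
      self$scope <- scope
      self$store <- store
      self$locks <- LockRegistry$new()
      private$props <- list()
      private$acts <- list()
      private$exts <- list()
      private$records <- new.env(parent = emptyenv())
      private$record_order <- character(0)
      private$buffer <- new.env(parent = emptyenv())
      private$buffer$index <- 0L
      private$buffer$jpeg <- NULL
      private$queue <- list()
      private$qresp <- list()
      private$nstream <- 0L
    },

    # ---- affordance registration -------------------------------------

    #' @description Register a property affordance.
    #' @param name Unique property name.
    #' @param getter Zero-argument function returning the value.
    #' @param setter One-argument function storing a new value, or `NULL`
    #'   for a read-only property.
    #' @param type JSON type descriptor: "number", "integer", "string",
    #'   "boolean", "object" or "array".
    #' @param description Human-readable description.
    #' @param extension Owning extension name or `NULL` (core).
    add_property = function(name, getter, setter = NULL, type = "number",
                            description = "", extension = NULL) {
      if (name %in% names(private$props))
        stop("property already registered: ", name, call. = FALSE)
      private$props[[name]] <- list(name = name, getter = getter,
                                    setter = setter, type = type,
                                    read_only = is.null(setter),
                                    description = description,
                                    extension = extension,
                                    href = paste0("/properties/", name))
      invisible(self)
    },

    #' @description Register an action affordance.
    #' @param name Unique action name.
    #' @param func `function(args, ctx)` implementing the action. `ctx` has
    #'   `checkpoint()` and `progress(frac)`.
    #' @param input Named list of argument type descriptors.
    #' @param locks Character vector of hardware locks the action needs.
    #' @param description Human-readable description.
    #' @param extension Owning extension name or `NULL` (core).
    add_action = function(name, func, input = list(), locks = character(0),
                          description = "", extension = NULL) {
      if (name %in% names(private$acts))
        stop("action already registered: ", name, call. = FALSE)
      href <- if (is.null(extension)) paste0("/actions/", name)
              else sprintf("/extensions/%s/actions/%s", extension, name)
      private$acts[[name]] <- list(name = name, func = func, input = input,
                                   locks = locks, description = description,
                                   extension = extension, href = href)
      invisible(self)
    },

    #' @description Register an extension: a named bundle of actions and
    #'   properties exposed under `/extensions/<name>/...`, included in the
    #'   Thing Description and OpenAPI documents, with direct access to the
    #'   hardware objects under the same lock discipline.
    #' @param name Unique extension name.
    #' @param actions Named list; each element a list with `func` and
    #'   optionally `input`, `locks`, `description`.
    #' @param properties Named list; each element a list with `getter` and
    #'   optionally `setter`, `type`, `description`.
    register_extension = function(name, actions = list(), properties = list()) {
      if (name %in% names(private$exts))
        stop("extension already registered: ", name, call. = FALSE)
      private$exts[[name]] <- list(name = name,
                                   actions = names(actions),
                                   properties = names(properties))
      for (an in names(actions)) {
        a <- actions[[an]]
        self$add_action(an, a$func,
                        input = a$input %||% list(),
                        locks = a$locks %||% character(0),
                        description = a$description %||% "",
                        extension = name)
      }
      for (pn in names(properties)) {
        p <- properties[[pn]]
        self$add_property(pn, p$getter, setter = p$setter,
                          type = p$type %||% "number",
                          description = p$description %||% "",
                          extension = name)
      }
      invisible(self)
    },

    #' @description Names of registered extensions.
    extensions = function() names(private$exts),
    #' @description Property descriptors (internal surface for tests).
    properties = function() private$props,
    #' @description Action descriptors.
    actions = function() private$acts,

    #' @description Dispatch one HTTP-style request against the Thing.
    #'   Delegates to [handle_request()].
    #' @param method HTTP method ("GET", "PUT", "POST", "DELETE").
    #' @param path URL path.
    #' @param body Request body as a JSON string, or `NULL`.
    handle = function(method, path, body = NULL) {
      handle_request(self, method, path, body)
    },

    # ---- action lifecycle --------------------------------------------

    #' @description Create a pending action record (does not run it).
    #'   Refused with a `vs_busy` error when a required hardware lock is
    #'   held by a running action.
    #' @param name Action name.
    #' @param args Named list of arguments.
    invoke = function(name, args = list()) {
      act <- private$acts[[name]]
      if (is.null(act)) stop("unknown action: ", name, call. = FALSE)
      bad <- setdiff(names(args), names(act$input))
      if (length(bad))
        stop(vs_error("vs_invalid_args",
                      paste("unknown argument(s):", paste(bad, collapse = ", "))))
      for (an in names(args)) {
        if (!validate_value(act$input[[an]], args[[an]]))
          stop(vs_error("vs_invalid_args",
                        sprintf("argument '%s' does not validate as %s",
                                an, act$input[[an]])))
      }
      for (lk in act$locks) {
        h <- self$locks$holder_of(lk)
        if (!is.null(h)) {
          rec <- private$records[[h]]
          if (!is.null(rec) && rec$state == "running")
            stop(vs_error("vs_busy",
                          sprintf("hardware lock '%s' is held by action %s", lk, h),
                          lock = lk, held_by = h))
        }
      }
      private$ninvoked <- private$ninvoked + 1L
      id <- sprintf("act-%06d", private$ninvoked)
      rec <- list(id = id, action = name, state = "pending", progress = 0,
                  input = args, output = NULL, error = NULL,
                  href = paste0("/action-records/", id),
                  created = now_iso(), started = NULL, ended = NULL,
                  cancel_requested = FALSE)
      private$records[[id]] <- rec
      private$record_order <- c(private$record_order, id)
      private$gc_records()
      rec
    },

    #' @description Execute one pending record to a terminal state.
    #' @param id Record id.
    run_record = function(id) {
      rec <- private$records[[id]]
      if (is.null(rec) || rec$state != "pending") return(invisible(NULL))
      if (!is.null(private$running)) {
        return(invisible(NULL))   # never interleave two actions
      }
      act <- private$acts[[rec$action]]
      for (lk in act$locks) {
        if (!self$locks$acquire(lk, id)) {
          rec$state <- "error"
          rec$error <- sprintf("hardware lock '%s' unavailable", lk)
          rec$ended <- now_iso()
          private$records[[id]] <- rec
          self$locks$release_all(id)
          return(invisible(rec))
        }
      }
      rec$state <- "running"; rec$started <- now_iso()
      private$records[[id]] <- rec
      private$running <- id
      thing <- self
      ctx <- list(
        checkpoint = function() {
          thing$pump()
          r <- thing$record(id)
          if (isTRUE(r$cancel_requested))
            stop(vs_error("vs_cancelled", "action cancelled"))
          invisible(NULL)
        },
        progress = function(frac) {
          r <- thing$record(id)
          r$progress <- max(0, min(1, frac))
          thing$set_record(r)
          invisible(NULL)
        })
      res <- tryCatch(list(ok = act$func(rec$input, ctx)),
                      vs_cancelled = function(e) list(cancelled = TRUE),
                      error = function(e) list(err = conditionMessage(e)))
      private$running <- NULL
      self$locks$release_all(id)
      rec <- private$records[[id]]
      rec$ended <- now_iso()
      if (!is.null(res$cancelled)) {
        rec$state <- "cancelled"
      } else if (!is.null(res$err)) {
        rec$state <- "error"; rec$error <- res$err
      } else {
        rec$state <- "completed"; rec$output <- res$ok; rec$progress <- 1
      }
      private$records[[id]] <- rec
      invisible(rec)
    },

    #' @description Run every pending record, in creation order.
    run_pending = function() {
      for (id in private$record_order) {
        rec <- private$records[[id]]
        if (!is.null(rec) && rec$state == "pending") self$run_record(id)
      }
      invisible(NULL)
    },

    #' @description Request cancellation of a record.
    #' @param id Record id.
    #' @return `"cancelled"` (pending records cancel immediately),
    #'   `"requested"` (running; takes effect at the next checkpoint) or
    #'   `"conflict"` (already terminal).
    cancel = function(id) {
      rec <- private$records[[id]]
      if (is.null(rec)) return("unknown")
      if (rec$state == "pending") {
        rec$state <- "cancelled"; rec$ended <- now_iso()
        private$records[[id]] <- rec
        return("cancelled")
      }
      if (rec$state == "running") {
        rec$cancel_requested <- TRUE
        private$records[[id]] <- rec
        return("requested")
      }
      "conflict"
    },

    #' @description Fetch a record by id (`NULL` if unknown).
    #' @param id Record id.
    record = function(id) private$records[[id]],
    #' @description Overwrite a record (internal).
    #' @param rec Record list (must carry `id`).
    set_record = function(rec) { private$records[[rec$id]] <- rec; invisible(NULL) },
    #' @description All record ids in creation order.
    record_ids = function() private$record_order,
    #' @description Id of the currently running record, or `NULL`.
    running_record = function() private$running,

    # ---- cooperative pump & streaming --------------------------------

    #' @description Pump: produce a frame for stream clients (if any are
    #'   connected) and service externally queued requests. Called at every
    #'   action checkpoint and safe to call any time.
    pump = function() {
      if (private$nstream > 0L && !is.null(self$scope)) self$produce_frame()
      if (!is.null(private$pump_hook)) private$pump_hook()
      if (length(private$queue)) {
        q <- private$queue; private$queue <- list()
        for (item in q) {
          private$qresp[[item$tag]] <-
            self$handle(item$method, item$path, item$body)
        }
      }
      invisible(NULL)
    },

    #' @description Install a pump hook (used by the HTTP server loop to
    #'   service sockets during running actions).
    #' @param fn Zero-argument function or `NULL`.
    set_pump_hook = function(fn) { private$pump_hook <- fn; invisible(self) },

    #' @description Queue a request to be answered at the next pump; the
    #'   response is retrieved with `queued_response(tag)`. This is how
    #'   tests exercise liveness during running actions without sockets.
    #' @param tag Unique tag for retrieval.
    #' @param method,path,body Request triple.
    enqueue_request = function(tag, method, path, body = NULL) {
      private$queue[[length(private$queue) + 1L]] <-
        list(tag = tag, method = method, path = path, body = body)
      invisible(self)
    },
    #' @description Response for a queued request (`NULL` until pumped).
    #' @param tag Tag passed to `enqueue_request`.
    queued_response = function(tag) private$qresp[[tag]],

    #' @description Render the current view into the frame buffer and bump
    #'   the frame index.
    produce_frame = function() {
      fr <- self$scope$grab_frame()
      private$buffer$index <- private$buffer$index + 1L
      private$buffer$jpeg <- fr$encoded
      invisible(private$buffer$index)
    },
    #' @description Current `(index, jpeg)` of the frame buffer.
    frame_buffer = function() list(index = private$buffer$index,
                                   jpeg = private$buffer$jpeg),

    #' @description Open an in-process MJPEG stream client. The client's
    #'   `next_frame()` returns `list(index, jpeg)` for a frame it has not
    #'   seen yet — never a duplicate, indices strictly increasing — or
    #'   `NULL` when no newer frame exists. A slow client simply polls less
    #'   often and receives a subsequence.
    open_stream = function() {
      private$nstream <- private$nstream + 1L
      thing <- self
      last <- private$buffer$index
      closed <- FALSE
      list(
        next_frame = function() {
          if (closed) stop("stream closed", call. = FALSE)
          fb <- thing$frame_buffer()
          if (fb$index > last) { last <<- fb$index; fb } else NULL
        },
        close = function() {
          if (!closed) {
            closed <<- TRUE
            thing$stream_closed()
          }
          invisible(NULL)
        })
    },
    #' @description Bookkeeping callback used by stream clients.
    stream_closed = function() {
      private$nstream <- max(0L, private$nstream - 1L)
      invisible(NULL)
    },
    #' @description Number of connected stream clients.
    stream_client_count = function() private$nstream
  ),
  private = list(
    props = NULL, acts = NULL, exts = NULL,
    records = NULL, record_order = NULL, running = NULL, ninvoked = 0L,
    buffer = NULL, queue = NULL, qresp = NULL,
    pump_hook = NULL, nstream = 0L,
    gc_records = function() {
      ids <- private$record_order
      terminal <- vapply(ids, function(i) {
        s <- private$records[[i]]$state
        s %in% c("completed", "cancelled", "error")
      }, logical(1))
      excess <- sum(terminal) - self$record_retention
      if (excess > 0) {
        drop <- ids[terminal][seq_len(excess)]
        for (i in drop) rm(list = i, envir = private$records)
        private$record_order <- setdiff(ids, drop)
      }
    }
  )
)

`%||%` <- function(a, b) if (is.null(a)) b else a

now_iso <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")

vs_error <- function(class, message, ...) {
  structure(class = c(class, "error", "condition"),
            c(list(message = message, call = NULL), list(...)))
}

validate_value <- function(type, v) {
  switch(type,
    number  = is.numeric(v) && length(v) == 1 && is.finite(v),
    integer = is.numeric(v) && length(v) == 1 && is.finite(v) &&
              abs(v - round(v)) < 1e-9,
    string  = is.character(v) && length(v) == 1,
    boolean = is.logical(v) && length(v) == 1 && !is.na(v),
    object  = is.list(v),
    array   = is.numeric(v) || is.list(v),
    TRUE)
}
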