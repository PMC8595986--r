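# Minimal HTTP/1.1 layer over base R sockets. No HTTP server or client
# package ships with this stack, so both ends are implemented here: enough
# of HTTP/1.1 for JSON request/response bodies, binary downloads and
# multipart MJPEG streaming. Connections are handled one request at a time
# (Connection: close), except stream connections which stay open and are
# fed from the frame buffer.

read_http_head <- function(con, max_bytes = 16384L) {
  # read byte-wise until CRLFCRLF (headers are tiny; robustness over speed)
  buf <- raw(0)
  while (length(buf) < max_bytes) {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0) break
    buf <- c(buf, b)
    n <- length(buf)
    if (n >= 4 && identical(buf[(n - 3):n], as.raw(c(13, 10, 13, 10))))
      break
  }
  if (!length(buf)) return(NULL)
  lines <- strsplit(rawToChar(buf), "\r\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(NULL)
  headers <- list()
  for (l in lines[-1]) {
    kv <- regmatches(l, regexpr(":", l, fixed = TRUE), invert = TRUE)[[1]]
    if (length(kv) == 2)
      headers[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  list(start = lines[1], headers = headers)
}

read_http_body <- function(con, headers) {
  len <- suppressWarnings(as.integer(headers[["content-length"]] %||% "0"))
  if (is.na(len) || len <= 0) return(NULL)
  buf <- raw(0)
  while (length(buf) < len) {
    chunk <- readBin(con, "raw", n = len - length(buf))
    if (!length(chunk)) break
    buf <- c(buf, chunk)
  }
  rawToChar(buf)
}

http_response_bytes <- function(resp) {
  body <- if (!is.null(resp$raw)) resp$raw
          else charToRaw(to_json_body(resp$json))
  status_text <- c(`200` = "OK", `201` = "Created", `202` = "Accepted",
                   `400` = "Bad Request", `404` = "Not Found",
                   `405` = "Method Not Allowed", `409` = "Conflict",
                   `500` = "Internal Server Error")
  st <- as.character(resp$status)
  head <- sprintf("HTTP/1.1 %s %s\r\n", st,
                  status_text[[st]] %||% "Unknown")
  hdrs <- c(sprintf("Content-Type: %s", resp$content_type %||% "application/json"),
            sprintf("Content-Length: %d", length(body)),
            "Connection: close")
  for (hn in names(resp$headers %||% list()))
    hdrs <- c(hdrs, sprintf("%s: %s", hn, resp$headers[[hn]]))
  c(charToRaw(paste0(head, paste(hdrs, collapse = "\r\n"), "\r\n\r\n")), body)
}

#' Run the Web-of-Things HTTP server
#'
#' Serves a [Thing] over HTTP/1.1 on `host:port`. The loop accepts one
#' connection at a time; `GET /stream` connections are kept open and fed
#' multipart JPEG parts (`boundary=frame`, each part carrying an
#' `X-Frame-Index` header) from the Thing's frame buffer — frames a slow
#' client misses are dropped, never repeated. While an action runs, the
#' server services sockets from the action's checkpoints, so property
#' reads, cancellations and the stream stay responsive during long
#' operations, and a conflicting hardware action is answered 409.
#'
#' Every request and action state transition is logged to `log_con`.
#' mDNS announcement is off by default and is not implemented in this
#' package (the flag is accepted for configuration compatibility and
#' ignored with a message).
#'
#' @param thing A [Thing].
#' @param host Bind address (server sockets bind all interfaces in base R;
#'   the host is used for logging only).
#' @param port TCP port.
#' @param max_requests Stop after this many non-stream requests (default
#'   `Inf`; used by tests and demos).
#' @param announce_mdns Accepted and ignored (no announcement is made).
#' @param log_con Connection for request logs (default [stderr()]).
#' @return Invisibly, the number of requests served.
#' @export
run_server <- function(thing, host = "127.0.0.1", port = 9393,
                       max_requests = Inf, announce_mdns = FALSE,
                       log_con = stderr()) {
  if (isTRUE(announce_mdns))
    message("mDNS announcement is not implemented; continuing without it")
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  streams <- list()     # list of list(con, last_index)
  served <- 0L
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...), file = log_con)
  logf("serving %s on %s:%d", thing$title, host, port)

  feed_streams <- function() {
    if (!length(streams)) return(invisible(NULL))
    fb <- thing$frame_buffer()
    if (is.null(fb$jpeg)) return(invisible(NULL))
    keep <- rep(TRUE, length(streams))
    for (i in seq_along(streams)) {
      s <- streams[[i]]
      if (fb$index <= s$last) next
      part <- c(charToRaw(sprintf(
        "--frame\r\nContent-Type: image/jpeg\r\nContent-Length: %d\r\nX-Frame-Index: %d\r\n\r\n",
        length(fb$jpeg), fb$index)), fb$jpeg, charToRaw("\r\n"))
      ok <- tryCatch({ writeBin(part, s$con); TRUE },
                     error = function(e) FALSE)
      if (ok) streams[[i]]$last <<- fb$index else keep[i] <- FALSE
    }
    for (i in which(!keep)) tryCatch(close(streams[[i]]$con),
                                     error = function(e) NULL)
    streams <<- streams[keep]
    invisible(NULL)
  }

  service_once <- function(timeout = 0) {
    ready <- tryCatch(socketSelect(list(srv), timeout = timeout),
                      error = function(e) FALSE)
    if (isTRUE(ready[1])) {
      con <- tryCatch(socketAccept(srv, blocking = TRUE, open = "a+b",
                                   timeout = 10),
                      error = function(e) NULL)
      if (!is.null(con)) handle_conn(con)
    }
    feed_streams()
    invisible(NULL)
  }

  handle_conn <- function(con) {
    head <- tryCatch(read_http_head(con), error = function(e) NULL)
    if (is.null(head)) { tryCatch(close(con), error = function(e) NULL); return(invisible(NULL)) }
    req <- strsplit(head$start, " ", fixed = TRUE)[[1]]
    method <- req[1]; path <- req[2] %||% "/"
    body <- tryCatch(read_http_body(con, head$headers), error = function(e) NULL)
    resp <- tryCatch(thing$handle(method, path, body),
                     error = function(e)
                       list(status = 500L,
                            json = list(error = conditionMessage(e)),
                            content_type = "application/json"))
    logf("%s %s -> %d", method, path, resp$status)
    if (isTRUE(resp$stream)) {
      hdr <- paste0("HTTP/1.1 200 OK\r\n",
                    "Content-Type: ", resp$content_type, "\r\n",
                    "Connection: keep-alive\r\n\r\n")
      ok <- tryCatch({ writeBin(charToRaw(hdr), con); TRUE },
                     error = function(e) FALSE)
      if (ok) {
        streams[[length(streams) + 1L]] <<-
          list(con = con, last = thing$frame_buffer()$index)
        if (!is.null(thing$scope)) thing$produce_frame()
        feed_streams()
      } else tryCatch(close(con), error = function(e) NULL)
    } else {
      tryCatch(writeBin(http_response_bytes(resp), con),
               error = function(e) NULL)
      tryCatch(close(con), error = function(e) NULL)
      served <<- served + 1L
    }
    invisible(NULL)
  }

  thing$set_pump_hook(function() service_once(timeout = 0))
  on.exit(thing$set_pump_hook(NULL), add = TRUE)

  while (served < max_requests) {
    service_once(timeout = 0.2)
    thing$run_pending()           # execute actions between requests
    if (length(streams) && !is.null(thing$scope) &&
        is.null(thing$running_record())) {
      thing$produce_frame()       # idle: keep the live stream moving
      feed_streams()
    }
  }
  invisible(served)
}

#' Issue a raw HTTP request (minimal client)
#'
#' @param host,port Server address.
#' @param method,path,body Request triple (`body` a JSON string or `NULL`).
#' @param timeout Socket timeout, seconds.
#' @return List: `status`, `headers`, `raw` body, and `json` (parsed when
#'   the content type is JSON).
#' @export
http_request <- function(host, port, method, path, body = NULL,
                         timeout = 10) {
  con <- socketConnection(host, port, blocking = TRUE, open = "a+b",
                          timeout = timeout)
  on.exit(tryCatch(close(con), error = function(e) NULL))
  payload <- if (is.null(body)) raw(0) else charToRaw(body)
  req <- sprintf("%s %s HTTP/1.1\r\nHost: %s:%d\r\nContent-Type: application/json\r\nContent-Length: %d\r\nConnection: close\r\n\r\n",
                 method, path, host, port, length(payload))
  writeBin(c(charToRaw(req), payload), con)
  head <- read_http_head(con)
  if (is.null(head)) stop("no response from server", call. = FALSE)
  status <- as.integer(strsplit(head$start, " ", fixed = TRUE)[[1]][2])
  len <- suppressWarnings(as.integer(head$headers[["content-length"]] %||% NA))
  buf <- raw(0)
  if (!is.na(len)) {
    while (length(buf) < len) {
      chunk <- readBin(con, "raw", n = len - length(buf))
      if (!length(chunk)) break
      buf <- c(buf, chunk)
    }
  } else {
    repeat {
      chunk <- readBin(con, "raw", n = 65536L)
      if (!length(chunk)) break
      buf <- c(buf, chunk)
    }
  }
  ctype <- head$headers[["content-type"]] %||% ""
  json <- if (grepl("application/json", ctype, fixed = TRUE) && length(buf))
    tryCatch(jsonlite::fromJSON(rawToChar(buf), simplifyVector = TRUE),
             error = function(e) NULL) else NULL
  list(status = status, headers = head$headers, raw = buf, json = json)
}
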