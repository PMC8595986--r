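#' Connect to a microscope and build a scripting proxy
#'
#' Fetches the server's Thing Description and converts the web API into
#' native R functions: one property accessor pair and one callable per
#' affordance, including everything provided by extensions. Calling an
#' action invokes it over the wire, polls its action resource until a
#' terminal state and returns the output (or raises a descriptive
#' condition); `blocking = FALSE` returns the record handle instead.
#'
#' `target` is either an `http://host:port` URL (transport: the package's
#' HTTP client) or a [Thing] object for in-process use — the request/
#' response semantics are identical, which is what makes the proxy's
#' transport transparency testable.
#'
#' Affordance titles are mangled into identifier-safe callable names
#' deterministically: lower-cased, every run of non-alphanumeric
#' characters becomes `_`, leading/trailing `_` stripped. The callables
#' live in `proxy$actions`, e.g. `proxy$actions$autofocus_fast(z_range =
#' 400)`.
#'
#' @param target Server URL or a [Thing].
#' @param poll_interval Initial poll interval, seconds (default 0.2;
#'   backs off exponentially to 2 s).
#' @return A `vs_proxy` object.
#' @examples
#' thing <- build_microscope_thing(virtual_microscope(seed = 1))
#' scopep <- connect(thing)
#' scopep$get_property("shutter_speed")
#' @export
connect <- function(target, poll_interval = 0.2) {
  transport <- if (inherits(target, "Thing")) local_transport(target)
               else http_transport(target)
  td_resp <- transport$request("GET", "/td")
  if (td_resp$status != 200 || is.null(td_resp$json))
    stop(vs_error("vs_protocol_error",
                  "could not fetch a Thing Description from the target"))
  td <- td_resp$json
  if (is.null(td$title) || is.null(td$properties))
    stop(vs_error("vs_protocol_error", "malformed Thing Description"))

  proxy <- new.env(parent = emptyenv())
  proxy$td <- td
  proxy$transport <- transport
  proxy$poll_interval <- poll_interval

  proxy$get_property <- function(name) {
    p <- td$properties[[name]]
    if (is.null(p)) stop("unknown property: ", name, call. = FALSE)
    r <- transport$request("GET", p$forms$href[[1]])
    if (r$status != 200) stop("property read failed: ", r$status, call. = FALSE)
    r$json
  }
  proxy$set_property <- function(name, value) {
    p <- td$properties[[name]]
    if (is.null(p)) stop("unknown property: ", name, call. = FALSE)
    r <- transport$request("PUT", p$forms$href[[1]],
                           body = to_json_body(value))
    if (r$status != 200)
      stop(sprintf("property write failed (%d): %s", r$status,
                   r$json$error %||% ""), call. = FALSE)
    r$json
  }
  proxy$call_action <- function(name, args = list(), blocking = TRUE) {
    a <- td$actions[[name]]
    if (is.null(a)) stop("unknown action: ", name, call. = FALSE)
    href <- a$forms$href[[1]]
    r <- transport$request("POST", href, body = to_json_body(args))
    if (r$status == 409)
      stop(vs_error("vs_busy",
                    sprintf("server busy: %s (lock '%s')",
                            r$json$error %||% "", r$json$lock %||% "?"),
                    lock = r$json$lock))
    if (r$status != 201)
      stop(sprintf("action invocation failed (%d): %s", r$status,
                   r$json$error %||% ""), call. = FALSE)
    rec <- r$json
    if (!blocking) return(rec)
    wait <- proxy$poll_interval
    repeat {
      if (rec$state %in% c("completed", "cancelled", "error")) break
      Sys.sleep(wait)
      wait <- min(2, wait * 1.5)
      pr <- transport$request("GET", rec$href)
      if (pr$status != 200)
        stop("action record vanished while polling", call. = FALSE)
      rec <- pr$json
    }
    if (rec$state == "cancelled")
      stop(vs_error("vs_cancelled_error",
                    sprintf("action '%s' was cancelled", name), record = rec))
    if (rec$state == "error")
      stop(vs_error("vs_action_error",
                    sprintf("action '%s' failed: %s", name,
                            rec$error %||% "unknown error"), record = rec))
    rec$output
  }

  proxy$actions <- list()
  for (an in names(td$actions)) {
    local({
      nm <- an
      proxy$actions[[mangle_name(nm)]] <<- function(..., .blocking = TRUE) {
        proxy$call_action(nm, args = list(...), blocking = .blocking)
      }
    })
  }
  class(proxy) <- "vs_proxy"
  proxy
}

#' @export
print.vs_proxy <- function(x, ...) {
  cat(sprintf("<microscope proxy '%s': %d properties, %d actions>\n",
              x$td$title, length(x$td$properties), length(x$td$actions)))
  invisible(x)
}

#' Deterministic affordance-name mangling
#'
#' @param x Affordance title.
#' @return Identifier-safe name.
#' @export
mangle_name <- function(x) {
  y <- gsub("[^a-z0-9]+", "_", tolower(x))
  gsub("^_+|_+$", "", y)
}

# in-process transport: dispatch against the Thing directly; after an
# invocation has been answered 201, run pending records so that a
# subsequent poll observes completion (the "background" of the
# cooperative model)
local_transport <- function(thing) {
  list(
    kind = "local",
    request = function(method, path, body = NULL) {
      resp <- thing$handle(method, path, body)
      if (identical(method, "POST") && identical(resp$status, 201L))
        thing$run_pending()
      json <- resp$json
      if (!is.null(json)) {
        # normalise through the serialised form so that local and HTTP
        # transports return identical structures
        json <- jsonlite::fromJSON(to_json_body(json), simplifyVector = TRUE)
      }
      list(status = as.integer(resp$status), json = json,
           raw = resp$raw %||% raw(0))
    })
}

http_transport <- function(url) {
  m <- regmatches(url, regexec("^http://([^:/]+):([0-9]+)/?$", url))[[1]]
  if (length(m) != 3)
    stop(vs_error("vs_connection_error",
                  paste("target must look like http://host:port, got", url)))
  host <- m[2]; port <- as.integer(m[3])
  list(
    kind = "http",
    host = host, port = port,
    request = function(method, path, body = NULL) {
      tryCatch(http_request(host, port, method, path, body),
               error = function(e)
                 stop(vs_error("vs_connection_error",
                               sprintf("request to %s:%d failed: %s",
                                       host, port, conditionMessage(e)))))
    })
}
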