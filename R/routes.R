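# HTTP-style router plus Thing Description / OpenAPI generation. The same
# dispatcher backs the in-process transport and the TCP server, so route
# behaviour is tested independently of sockets.

#' Dispatch an HTTP-style request against a Thing
#'
#' Routes:
#' * `GET /` — device summary with links
#' * `GET /td` — Thing Description
#' * `GET /openapi.json` — OpenAPI document
#' * `GET /properties`, `GET|PUT /properties/{name}`
#' * `GET /actions`, `GET|POST <action href>` (core actions live at
#'   `/actions/{name}`, extension actions at
#'   `/extensions/{ext}/actions/{name}`)
#' * `GET /action-records`, `GET|DELETE /action-records/{id}` (`DELETE`
#'   requests cancellation)
#' * `GET /captures`, `GET /captures/{id}` (raw JPEG download)
#' * `GET /stream` — marked `stream = TRUE` for transports that serve
#'   multipart MJPEG
#'
#' Status codes: 200 OK, 201 created (action invoked), 202 cancellation
#' requested, 400 invalid body/arguments, 404 unknown, 405 write to
#' read-only property / wrong method, 409 hardware busy or cancel conflict.
#'
#' @param thing A [Thing].
#' @param method HTTP method.
#' @param path URL path (no query strings are used by this API).
#' @param body JSON string or `NULL`.
#' @return List: `status`, `json` (R object to serialise) or `raw` (raw
#'   vector) plus `content_type`, and optionally `stream = TRUE`.
#' @export
handle_request <- function(thing, method, path, body = NULL) {
  path <- sub("\\?.*$", "", path)
  parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  props <- thing$properties()
  acts <- thing$actions()

  ok <- function(x, status = 200L) list(status = status, json = x,
                                        content_type = "application/json")
  err <- function(status, msg, ...) list(status = status,
                                         json = list(error = msg, ...),
                                         content_type = "application/json")
  parse_body <- function() {
    if (is.null(body) || !nzchar(body)) return(structure(list(), empty = TRUE))
    tryCatch(jsonlite::fromJSON(body, simplifyVector = TRUE),
             error = function(e) structure(list(), invalid = TRUE))
  }

  if (length(parts) == 0 || identical(parts, character(0))) {
    if (method != "GET") return(err(405L, "method not allowed"))
    return(ok(list(title = thing$title,
                   links = list(td = "/td", openapi = "/openapi.json",
                                properties = "/properties",
                                actions = "/actions", stream = "/stream"))))
  }

  head <- parts[1]

  if (head == "td" && length(parts) == 1) {
    if (method != "GET") return(err(405L, "method not allowed"))
    return(ok(thing_description(thing)))
  }
  if (head == "openapi.json" && length(parts) == 1) {
    if (method != "GET") return(err(405L, "method not allowed"))
    return(ok(openapi_description(thing)))
  }

  if (head == "properties") {
    if (length(parts) == 1) {
      if (method != "GET") return(err(405L, "method not allowed"))
      vals <- lapply(props, function(p) p$getter())
      return(ok(vals))
    }
    p <- props[[parts[2]]]
    if (is.null(p)) return(err(404L, paste("unknown property:", parts[2])))
    if (method == "GET") return(ok(p$getter()))
    if (method == "PUT") {
      if (p$read_only) return(err(405L, "property is read-only"))
      v <- parse_body()
      if (isTRUE(attr(v, "invalid")) || isTRUE(attr(v, "empty")))
        return(err(400L, "request body is not valid JSON"))
      if (!validate_value(p$type, v))
        return(err(400L, sprintf("value does not validate as %s", p$type)))
      bad <- tryCatch({ p$setter(v); NULL }, error = function(e) e)
      if (!is.null(bad)) return(err(400L, conditionMessage(bad)))
      return(ok(p$getter()))
    }
    return(err(405L, "method not allowed"))
  }

  # action paths: /actions/{name} or /extensions/{ext}/actions/{name}
  act <- NULL
  if (head == "actions" && length(parts) == 2) {
    act <- acts[[parts[2]]]
    if (is.null(act) || !is.null(act$extension))
      return(err(404L, paste("unknown action:", parts[2])))
  } else if (head == "extensions" && length(parts) == 4 &&
             parts[3] == "actions") {
    act <- acts[[parts[4]]]
    if (is.null(act) || !identical(act$extension, parts[2]))
      return(err(404L, paste("unknown extension action:", parts[4])))
  } else if (head == "extensions" && length(parts) == 1) {
    if (method != "GET") return(err(405L, "method not allowed"))
    return(ok(lapply(thing$extensions(), function(e) list(name = e))))
  }
  if (!is.null(act)) {
    if (method == "GET") {
      recs <- Filter(function(r) r$action == act$name,
                     lapply(thing$record_ids(), thing$record))
      return(ok(list(name = act$name, description = act$description,
                     input = act$input, href = act$href,
                     records = lapply(recs, record_json))))
    }
    if (method == "POST") {
      args <- parse_body()
      if (isTRUE(attr(args, "invalid")))
        return(err(400L, "request body is not valid JSON"))
      if (isTRUE(attr(args, "empty"))) args <- list()
      if (!is.list(args)) return(err(400L, "arguments must be a JSON object"))
      rec <- tryCatch(thing$invoke(act$name, args),
                      vs_busy = function(e) e,
                      vs_invalid_args = function(e) e)
      if (inherits(rec, "vs_busy"))
        return(err(409L, conditionMessage(rec), lock = rec$lock))
      if (inherits(rec, "vs_invalid_args"))
        return(err(400L, conditionMessage(rec)))
      resp <- ok(record_json(rec), status = 201L)
      resp$headers <- list(Location = rec$href)
      return(resp)
    }
    return(err(405L, "method not allowed"))
  }
  if (head == "actions" && length(parts) == 1) {
    if (method != "GET") return(err(405L, "method not allowed"))
    return(ok(lapply(acts, function(a)
      list(name = a$name, href = a$href, description = a$description))))
  }

  if (head == "action-records") {
    if (length(parts) == 1) {
      if (method != "GET") return(err(405L, "method not allowed"))
      return(ok(lapply(thing$record_ids(),
                       function(i) record_json(thing$record(i)))))
    }
    rec <- thing$record(parts[2])
    if (is.null(rec)) return(err(404L, paste("unknown record:", parts[2])))
    if (method == "GET") return(ok(record_json(rec)))
    if (method == "DELETE") {
      res <- thing$cancel(parts[2])
      if (res == "cancelled") return(ok(record_json(thing$record(parts[2]))))
      if (res == "requested") return(ok(record_json(thing$record(parts[2])),
                                        status = 202L))
      return(err(409L, "record is already terminal; cannot cancel"))
    }
    return(err(405L, "method not allowed"))
  }

  if (head == "captures") {
    if (is.null(thing$store)) return(err(404L, "no capture store configured"))
    if (length(parts) == 1) {
      if (method != "GET") return(err(405L, "method not allowed"))
      return(ok(lapply(unname(thing$store$list()), function(r)
        list(id = r$id, href = paste0("/captures/", r$id),
             file = basename(r$file_path), metadata = r$metadata,
             timestamp = r$timestamp))))
    }
    rec <- thing$store$get(parts[2])
    if (is.null(rec)) return(err(404L, paste("unknown capture:", parts[2])))
    if (method != "GET") return(err(405L, "method not allowed"))
    bytes <- readBin(rec$file_path, "raw",
                     n = file.info(rec$file_path)$size)
    return(list(status = 200L, raw = bytes, content_type = "image/jpeg"))
  }

  if (head == "stream" && length(parts) == 1) {
    if (method != "GET") return(err(405L, "method not allowed"))
    return(list(status = 200L, stream = TRUE,
                content_type = "multipart/x-mixed-replace; boundary=frame"))
  }

  err(404L, paste("no such route:", path))
}

record_json <- function(rec) {
  list(id = rec$id, action = rec$action, state = rec$state,
       progress = rec$progress, input = rec$input, output = rec$output,
       error = rec$error, href = rec$href, created = rec$created,
       started = rec$started, ended = rec$ended)
}

#' Thing Description document
#'
#' A minimal conformant subset of the W3C Thing Description vocabulary:
#' `title`, `securityDefinitions`/`security` (nosec), `properties` and
#' `actions` maps with type descriptors and one `forms` entry per
#' interaction giving its URL and operation. Extension-provided affordances
#' are included like any other; semantic-type annotation (`@type`) fields
#' are present but empty. Stable across calls while registrations are
#' unchanged.
#'
#' @param thing A [Thing].
#' @return Nested list ready for JSON serialisation.
#' @export
thing_description <- function(thing) {
  props <- lapply(thing$properties(), function(p) {
    list(title = p$name, `@type` = character(0), type = p$type,
         description = p$description, readOnly = p$read_only,
         forms = list(list(href = p$href,
                           op = if (p$read_only) list("readproperty")
                                else list("readproperty", "writeproperty"))))
  })
  acts <- lapply(thing$actions(), function(a) {
    list(title = a$name, `@type` = character(0),
         description = a$description,
         input = list(type = "object", properties = lapply(a$input, function(t)
           list(type = t))),
         forms = list(list(href = a$href, op = list("invokeaction"))))
  })
  list(`@context` = "https://www.w3.org/2019/wot/td/v1",
       title = thing$title,
       securityDefinitions = list(nosec_sc = list(scheme = "nosec")),
       security = "nosec_sc",
       properties = props,
       actions = acts,
       links = list(list(rel = "service-doc", href = "/openapi.json")))
}

#' OpenAPI description document
#'
#' Enumerates every HTTP endpoint the Thing serves (fixed routes, one path
#' per property, action and extension action) with its methods and
#' canned responses, under OpenAPI 3.0.3.
#'
#' @param thing A [Thing].
#' @return Nested list ready for JSON serialisation.
#' @export
openapi_description <- function(thing) {
  resp200 <- list(`200` = list(description = "OK"))
  op <- function(summary, responses = resp200)
    list(summary = summary, responses = responses)
  paths <- list()
  paths[["/"]] <- list(get = op("device summary"))
  paths[["/td"]] <- list(get = op("Thing Description"))
  paths[["/openapi.json"]] <- list(get = op("this document"))
  paths[["/properties"]] <- list(get = op("all property values"))
  for (p in thing$properties()) {
    methods <- list(get = op(paste("read property", p$name)))
    if (!p$read_only)
      methods$put <- op(paste("write property", p$name),
                        c(resp200, list(`400` = list(description = "invalid value"))))
    paths[[p$href]] <- methods
  }
  paths[["/actions"]] <- list(get = op("list actions"))
  for (a in thing$actions()) {
    paths[[a$href]] <- list(
      get = op(paste("describe action", a$name)),
      post = op(paste("invoke action", a$name),
                list(`201` = list(description = "action record created"),
                     `400` = list(description = "invalid arguments"),
                     `409` = list(description = "hardware busy"))))
  }
  paths[["/action-records"]] <- list(get = op("list action records"))
  paths[["/action-records/{id}"]] <- list(
    get = op("poll action record"),
    delete = op("cancel action",
                c(resp200, list(`409` = list(description = "already terminal")))))
  if (!is.null(thing$store)) {
    paths[["/captures"]] <- list(get = op("list captures with metadata"))
    paths[["/captures/{id}"]] <- list(get = op("download capture JPEG"))
  }
  paths[["/stream"]] <- list(get = op("MJPEG live stream"))
  list(openapi = "3.0.3",
       info = list(title = thing$title, version = "1.0.0"),
       paths = paths)
}

#' Serialise a route response body to JSON text
#'
#' @param x The `json` element of a [handle_request()] response.
#' @return A character scalar of JSON.
#' @export
to_json_body <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                                digits = NA, force = TRUE))
}
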