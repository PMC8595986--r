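#' Capture store
#'
#' Owns the on-disk layout of captured images: a root directory, one JPEG
#' per capture (scan captures live in one sub-directory per scan with
#' zero-padded site indices), and an in-memory index kept in lockstep with
#' the files. Every listed capture corresponds to exactly one decodable
#' file on disk at all times.
#' @export
CaptureStore <- R6::R6Class("CaptureStore",
  public = list(
    #' @field root Root directory.
    root = NULL,

    #' @description Create a store rooted at `root` (created if missing).
    #' @param root Directory path.
    initialize = function(root = tempfile("captures-")) {
      dir.create(root, recursive = TRUE, showWarnings = FALSE)
      self$root <- root
      private$index <- list()
      private$counter <- 0L
    },

    #' @description Register a capture; used by [capture_image()].
    #' @param bytes Raw JPEG (with EXIF) to write.
    #' @param metadata Parsed metadata document.
    #' @param subdir Optional sub-directory (scans).
    #' @param basename Optional file basename (without extension).
    add = function(bytes, metadata, subdir = NULL, basename = NULL) {
      private$counter <- private$counter + 1L
      id <- sprintf("cap-%06d", private$counter)
      dir <- self$root
      if (!is.null(subdir)) {
        dir <- file.path(self$root, subdir)
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      }
      fn <- file.path(dir, paste0(if (is.null(basename)) id else basename,
                                  ".jpg"))
      if (!dir.exists(dirname(fn)) || file.access(dirname(fn), 2) != 0)
        stop("capture store is not writable: ", dirname(fn), call. = FALSE)
      writeBin(bytes, fn)
      rec <- structure(list(id = id, file_path = fn, metadata = metadata,
                            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")),
                       class = "vs_capture")
      private$index[[id]] <- rec
      rec
    },

    #' @description All capture records, in capture order.
    list = function() private$index,

    #' @description Look up one record by id (`NULL` if absent).
    #' @param id Capture id.
    get = function(id) private$index[[id]]
  ),
  private = list(index = NULL, counter = NULL)
)

#' Capture an image with embedded metadata
#'
#' Renders a frame at the current stage position, builds the metadata
#' document (camera settings, stage position, calibration snapshot, any
#' user-supplied keys), serialises it to JSON and embeds it in the JPEG's
#' EXIF UserComment field, then writes the file into the store.
#'
#' Metadata schema (`virtuscope/1`): top-level keys `schema`, `time`,
#' `camera` (`shutter_speed_ms`, `frame_shape`, `jpeg_quality`), `stage`
#' (`position` x/y/z in steps), `calibration` (affine rows, backlash,
#' residual; `NULL` when uncalibrated) and `user` (the caller's document).
#'
#' @param scope A [VirtualMicroscope].
#' @param store A [CaptureStore].
#' @param user_metadata Named list of user keys (must be JSON-serialisable).
#' @param subdir,basename Passed to the store (used by scans).
#' @return A `vs_capture` record: `id`, `file_path`, `metadata`,
#'   `timestamp`.
#' @export
capture_image <- function(scope, store, user_metadata = list(),
                          subdir = NULL, basename = NULL) {
  if (length(user_metadata) && is.null(names(user_metadata)))
    stop("user_metadata must be a named list", call. = FALSE)
  fr <- scope$grab_frame()
  pos <- scope$position()
  meta <- list(
    schema = "virtuscope/1",
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
    camera = list(shutter_speed_ms = scope$camera$shutter_speed,
                  frame_shape = as.integer(scope$camera$frame_shape),
                  jpeg_quality = scope$camera$jpeg_quality),
    stage = list(position = list(x = pos[1], y = pos[2], z = pos[3])),
    calibration = if (is.null(scope$calibration)) NULL else list(
      A_rows = list(as.numeric(scope$calibration$A[1, ]),
                    as.numeric(scope$calibration$A[2, ])),
      backlash_steps = as.numeric(scope$calibration$backlash_est),
      residual_rms_px = scope$calibration$residual_rms),
    user = user_metadata)
  json <- tryCatch(
    as.character(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                  null = "null")),
    error = function(e) stop("metadata is not serialisable: ",
                             conditionMessage(e), call. = FALSE))
  bytes <- exif_embed(fr$encoded, json)
  store$add(bytes, meta, subdir = subdir, basename = basename)
}

#' Read back the metadata document embedded in a capture file
#'
#' @param path Path to a JPEG written by [capture_image()].
#' @return The parsed metadata list, or `NULL` if the file has none.
#' @export
read_capture_metadata <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  json <- exif_extract(bytes)
  if (is.null(json)) return(NULL)
  jsonlite::fromJSON(json, simplifyVector = TRUE)
}

#' @export
print.vs_capture <- function(x, ...) {
  cat(sprintf("<capture %s: %s>\n", x$id, x$file_path))
  invisible(x)
}
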