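#' Virtual three-axis translation stage
#'
#' Models an open-hardware flexure stage driven in integer motor steps, with
#' two controllable imperfections:
#'
#' * **Backlash** (lost motion): each axis has a dead band of width
#'   `backlash[i]` steps. When the commanded direction reverses, the first
#'   `backlash[i]` steps of travel take up slack and produce no actual
#'   motion; sustained travel in one direction is 1:1.
#' * **Jitter**: optional Gaussian positional noise (in steps) added to the
#'   effective position after every move, clamped to six sigma. Jitter is
#'   transient (it does not random-walk).
#'
#' The stage also carries the *hidden* ground-truth `true_affine` matrix
#' (camera pixels per motor step, 2x2) used by the virtual camera to render
#' frames. Calibration code must never read it; tests use it as ground truth.
#'
#' The dead-band model maintains a mechanism position `y` per axis with the
#' invariant `c - b <= y <= c` (`c` commanded, `b` backlash). A move to `c'`
#' updates `y' = min(max(y, c' - b), c')`. The initial slack state is
#' configurable: `"+"` (default) means slack is taken up in the positive
#' direction (`y = c - b`), `"-"` means `y = c`.
#'
#' @examples
#' st <- VirtualStage$new(backlash = c(10, 0, 0))
#' x0 <- st$actual()[1]
#' st$move_to(c(100, 0, 0)); st$move_to(c(0, 0, 0))
#' st$actual()[1] - x0  # 10: the reversal lost one dead-band of travel
#' @export
VirtualStage <- R6::R6Class("VirtualStage",
  public = list(
    #' @field backlash Non-negative per-axis dead-band width, steps.
    backlash = NULL,
    #' @field jitter_sigma Per-move positional noise sigma, steps.
    jitter_sigma = 0,
    #' @field true_affine Hidden 2x2 ground-truth matrix, camera px per step.
    true_affine = NULL,
    #' @field limits Symmetric travel limit per axis, steps.
    limits = 1e6,
    #' @field command_log Data frame of every commanded move (for lock-safety
    #'   and concurrency analysis).
    command_log = NULL,

    #' @description Create a stage.
    #' @param backlash Numeric length-3, non-negative, steps.
    #' @param jitter_sigma Single non-negative number, steps.
    #' @param true_affine Non-singular 2x2 matrix, px per step.
    #' @param seed Seed for the stage's private jitter RNG stream.
    #' @param slack One of `"+"`, `"-"`: initial slack state.
    initialize = function(backlash = c(0, 0, 0), jitter_sigma = 0,
                          true_affine = diag(2), seed = 1L, slack = "+") {
      stopifnot(length(backlash) == 3, all(backlash >= 0),
                length(jitter_sigma) == 1, jitter_sigma >= 0,
                identical(dim(true_affine), c(2L, 2L)))
      if (abs(det(true_affine)) < 1e-9)
        stop("true_affine must be non-singular", call. = FALSE)
      self$backlash <- as.numeric(backlash)
      self$jitter_sigma <- jitter_sigma
      self$true_affine <- true_affine
      private$cmd <- c(0L, 0L, 0L)
      private$mech <- if (identical(slack, "+")) -self$backlash else c(0, 0, 0)
      private$jit <- c(0, 0, 0)
      private$rng <- make_rng(seed)
      self$command_log <- list()
    },

    #' @description Absolute move. Non-integer targets are rejected.
    #' @param target Length-3 integer-valued vector `(x, y, z)` in steps.
    #' @param holder Optional label recorded in the command log.
    move_to = function(target, holder = NA_character_) {
      if (length(target) != 3 || any(is.na(target)) ||
          any(abs(target - round(target)) > 1e-9)) {
        stop("stage target must be three integer step counts", call. = FALSE)
      }
      target <- as.numeric(round(target))
      if (any(abs(target) > self$limits))
        stop("stage target outside travel limits", call. = FALSE)
      b <- self$backlash
      private$mech <- pmin(pmax(private$mech, target - b), target)
      private$cmd <- target
      if (self$jitter_sigma > 0) {
        e <- private$rng(function() stats::rnorm(3, 0, self$jitter_sigma))
        private$jit <- pmin(pmax(e, -6 * self$jitter_sigma), 6 * self$jitter_sigma)
      }
      self$command_log[[length(self$command_log) + 1L]] <-
        list(target = target, holder = holder, time = Sys.time())
      invisible(self)
    },

    #' @description Relative move in steps.
    #' @param delta Length-3 integer-valued displacement.
    #' @param holder Optional label recorded in the command log.
    move_rel = function(delta, holder = NA_character_) {
      self$move_to(private$cmd + delta, holder = holder)
    },

    #' @description Commanded position (integer steps).
    commanded = function() private$cmd,

    #' @description Effective (actual) position including slack and jitter.
    actual = function() private$mech + private$jit
  ),
  private = list(cmd = NULL, mech = NULL, jit = NULL, rng = NULL)
)

#' Move a virtual stage (functional wrapper)
#'
#' @param stage A [VirtualStage].
#' @param target Length-3 integer step target `(x, y, z)`.
#' @return The updated stage, invisibly.
#' @export
move_stage <- function(stage, target) {
  stage$move_to(target)
  invisible(stage)
}

# private RNG stream: returns fun(thunk) evaluating thunk under the stream
# without touching the global .Random.seed
make_rng <- function(seed) {
  state <- local({
    with_seed(as.integer(seed), NULL)
    # capture a fresh state derived from seed
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    s
  })
  function(thunk) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (had) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
    thunk()
  }
}
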