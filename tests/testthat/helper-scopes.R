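# Shared fixtures: all synthetic, built in code at test time.

# small, fast microscope: 512 px sample is plenty for local moves
test_scope <- function(density = 0.8, seed = 1L, sample_shape = c(512, 512),
                       ...) {
  sc <- virtual_microscope(density = density, seed = seed,
                           sample_shape = sample_shape, ...)
  sc$move_to(c(0, 0, sc$camera$z_focus))
  sc
}

# a context whose checkpoint cancels by raising the cooperative
# cancellation condition after `after` checkpoints
cancelling_ctx <- function(after) {
  n <- 0L
  list(checkpoint = function() {
    n <<- n + 1L
    if (n > after)
      stop(structure(class = c("vs_cancelled", "error", "condition"),
                     list(message = "cancelled by test", call = NULL)))
  },
  progress = function(frac) invisible(NULL))
}

expect_error_class <- function(expr, class) {
  err <- tryCatch({ expr; NULL }, error = function(e) e)
  expect_false(is.null(err), label = "expression raised an error")
  expect_s3_class(err, class)
  invisible(err)
}
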