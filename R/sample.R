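#' Generate a deterministic synthetic sample
#'
#' Produces the ground-truth scene the virtual camera images: a field larger
#' than one camera field of view, populated with smooth blob-like features and
#' fine texture. The `density` parameter controls how feature-rich the scene
#' is: `density = 0` is a perfectly uniform (blank) field, useful for
#' flat-field work; high densities give the high-spatial-frequency content
#' that sharpness metrics and displacement measurement rely on.
#'
#' The same `(seed, density, shape)` always reproduces the identical array,
#' bit for bit; the generator uses its own RNG stream and does not disturb
#' the session's `.Random.seed`.
#'
#' @param seed Integer RNG seed.
#' @param density Feature density in `[0, 1]`.
#' @param shape Integer `(height, width)` of the scene in pixels. Must be at
#'   least four times the camera field of view in each dimension for use with
#'   [render_frame()]; the default suits the default camera.
#' @return An object of class `vs_sample`: a list with `pixels` (a
#'   `height x width x 3` array in `[0, 1]`), `density`, `seed` and `shape`.
#' @examples
#' s <- generate_sample(seed = 1, density = 0.5, shape = c(256, 256))
#' range(s$pixels)
#' @export
generate_sample <- function(seed, density, shape = c(1024, 1024)) {
  if (!is.numeric(density) || length(density) != 1 || is.na(density) ||
      density < 0 || density > 1) {
    stop("`density` must be a single number in [0, 1]", call. = FALSE)
  }
  if (length(shape) != 2 || any(shape < 8)) {
    stop("`shape` must be (height, width) with both >= 8", call. = FALSE)
  }
  seed <- as.integer(seed)
  shape <- as.integer(round(shape))
  h <- shape[1]; w <- shape[2]

  base <- 0.5
  if (density == 0) {
    px <- array(base, dim = c(h, w, 3))
  } else {
    px <- with_seed(seed, {
      # impulse field convolved with two Gaussian kernels: coarse blobs plus
      # fine speckle; both counts scale with density
      n_blob <- max(1L, round(density * h * w / 900))
      n_fine <- max(1L, round(density * h * w / 250))
      field <- matrix(0, h, w)
      idx <- cbind(sample.int(h, n_blob, replace = TRUE),
                   sample.int(w, n_blob, replace = TRUE))
      field[idx] <- field[idx] + stats::runif(n_blob, -1, 1) * 18
      blobs <- EBImage::filter2(field, gauss_kernel(2.5))

      fine <- matrix(0, h, w)
      idx2 <- cbind(sample.int(h, n_fine, replace = TRUE),
                    sample.int(w, n_fine, replace = TRUE))
      fine[idx2] <- fine[idx2] + stats::runif(n_fine, -1, 1) * 3.2
      fine <- EBImage::filter2(fine, gauss_kernel(0.8))

      scene <- base + blobs + fine
      # per-channel weights keep channels correlated but distinct
      wts <- c(1, 0.85, 0.7)
      out <- array(0, dim = c(h, w, 3))
      for (k in 1:3) out[, , k] <- pmin(1, pmax(0, base + (scene - base) * wts[k]))
      out
    })
  }
  structure(list(pixels = px, density = density, seed = seed, shape = shape),
            class = "vs_sample")
}

#' @export
print.vs_sample <- function(x, ...) {
  cat(sprintf("<vs_sample %dx%d, density %.2f, seed %d>\n",
              x$shape[1], x$shape[2], x$density, x$seed))
  invisible(x)
}

#' Save / load a synthetic sample as PNG
#'
#' The pixel array round-trips through 16-bit PNG; `density` and `seed` are
#' not stored in the file and are set to `NA` on load.
#' @param sample A `vs_sample`.
#' @param path File path.
#' @export
save_sample_png <- function(sample, path) {
  png::writePNG(sample$pixels, target = path)
  invisible(path)
}

#' @rdname save_sample_png
#' @export
load_sample_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3]
  structure(list(pixels = px, density = NA_real_, seed = NA_integer_,
                 shape = dim(px)[1:2]),
            class = "vs_sample")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# normalised Gaussian kernel matrix, odd size covering +-3 sigma
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  k <- outer(stats::dnorm(x, sd = sigma), stats::dnorm(x, sd = sigma))
  k / sum(k)
}
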