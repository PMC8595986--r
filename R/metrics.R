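#' Convert a colour image to greyscale
#'
#' Weighted channel sum with the ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114). The weights sum to one, so a channel-constant
#' image maps to the same constant and output stays within `[0, 1]`.
#'
#' @param frame_pixels h x w x 3 array in `[0, 1]`.
#' @return h x w numeric matrix.
#' @export
to_grayscale <- function(frame_pixels) {
  d <- dim(frame_pixels)
  if (length(d) != 3 || d[3] != 3)
    stop("expected a 3-channel (h x w x 3) array", call. = FALSE)
  0.299 * frame_pixels[, , 1] + 0.587 * frame_pixels[, , 2] +
    0.114 * frame_pixels[, , 3]
}

#' Laplacian sharpness score
#'
#' Convolves the image with the 4-neighbour Laplacian kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]` (zero padding at the borders), raises the
#' response to the fourth power and sums over all pixels. The fourth power
#' weights strong, sharp edges heavily relative to low-amplitude noise,
#' which makes the score a robust focus metric: it is maximal when fine
#' detail is in focus and decays as defocus blur spreads edges out.
#'
#' Border handling: the kernel response is summed over the interior (valid)
#' region only, i.e. pixels where the full 3 x 3 kernel fits. This keeps the
#' score zero for constant images and invariant under adding a constant,
#' which padded variants violate at the borders.
#'
#' Properties: a constant image scores exactly 0; adding a constant leaves
#' the score unchanged; scaling the image by `s >= 0` scales the score by
#' `s^4`.
#'
#' @param gray 2D numeric matrix, at least 3 x 3.
#' @return Single non-negative number.
#' @export
laplacian_sharpness <- function(gray) {
  if (!is.matrix(gray) || nrow(gray) < 3 || ncol(gray) < 3)
    stop("`gray` must be a matrix at least 3x3", call. = FALSE)
  h <- nrow(gray); w <- ncol(gray)
  lap <- gray[1:(h - 2), 2:(w - 1)] + gray[3:h, 2:(w - 1)] +
         gray[2:(h - 1), 1:(w - 2)] + gray[2:(h - 1), 3:w] -
         4 * gray[2:(h - 1), 2:(w - 1)]
  sum(lap^4)
}

#' Measure sub-pixel displacement between two frames
#'
#' Phase correlation: both images are Hann-windowed (suppressing wrap-around
#' artefacts), the cross-power spectrum is whitened and band-limited to the
#' lower 60% of each axis's frequency range (high-frequency phases carry
#' mostly interpolation and compression noise once whitened), and the
#' correlation peak is located to integer precision. The sub-pixel position
#' is then refined by evaluating the inverse DFT on a 1/32-px grid within
#' +-1 px of the peak (a matrix-multiply local DFT, the standard upsampled
#' cross-correlation refinement).
#'
#' Returns `(dx, dy)` in pixels such that the content of `frame_a` appears
#' in `frame_b` shifted by `+dx` columns (rightward) and `+dy` rows
#' (downward); `measure_displacement(a, b) == -measure_displacement(b, a)`.
#'
#' Confidence is assessed by the peak-to-sidelobe ratio of the correlation
#' surface (peak over the 99.5th percentile outside a 5 px exclusion zone).
#' Featureless input pairs produce an indistinct peak and raise a
#' `vs_low_confidence` error carrying the ratio as a diagnostic.
#'
#' @param frame_a,frame_b Equal-shape 2D matrices (greyscale images).
#' @param min_psr Minimum peak-to-sidelobe ratio accepted (default 4).
#' @param band Fraction of the frequency range kept per axis (default 0.6).
#' @param upsample Sub-pixel refinement factor (default 32).
#' @return Numeric `c(dx, dy)` with attribute `psr`.
#' @export
measure_displacement <- function(frame_a, frame_b, min_psr = 4, band = 0.6,
                                 upsample = 32) {
  if (!is.matrix(frame_a) || !is.matrix(frame_b) ||
      !identical(dim(frame_a), dim(frame_b)))
    stop("frames must be matrices of identical shape", call. = FALSE)
  h <- nrow(frame_a); w <- ncol(frame_a)

  win <- hann2d(h, w)
  fa <- stats::fft((frame_a - mean(frame_a)) * win)
  fb <- stats::fft((frame_b - mean(frame_b)) * win)
  cross <- fb * Conj(fa)
  cross <- cross / pmax(Mod(cross), 1e-12)
  kr <- c(0:floor((h - 1) / 2), -(ceiling((h - 1) / 2):1))
  kc <- c(0:floor((w - 1) / 2), -(ceiling((w - 1) / 2):1))
  keep <- outer(abs(kr) / h <= band * 0.5, abs(kc) / w <= band * 0.5)
  cross[!keep] <- 0
  corr <- Re(stats::fft(cross, inverse = TRUE)) / (h * w)

  pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  pr <- pk[1]; pc <- pk[2]

  # peak-to-sidelobe: compare against the high quantile outside +-5 px
  dr <- pmin(abs(seq_len(h) - pr), h - abs(seq_len(h) - pr))
  dc <- pmin(abs(seq_len(w) - pc), w - abs(seq_len(w) - pc))
  excl <- outer(dr <= 5, dc <= 5, `&`)
  side <- stats::quantile(abs(corr[!excl]), 0.995, names = FALSE)
  psr <- corr[pr, pc] / max(side, 1e-12)
  if (!is.finite(psr) || psr < min_psr) {
    cond <- structure(
      class = c("vs_low_confidence", "error", "condition"),
      list(message = sprintf(
        "displacement measurement low confidence (peak-to-sidelobe %.2f < %.2f)",
        psr, min_psr), call = NULL, psr = psr))
    stop(cond)
  }

  dy0 <- pr - 1; if (dy0 > h / 2) dy0 <- dy0 - h
  dx0 <- pc - 1; if (dx0 > w / 2) dx0 <- dx0 - w
  u <- dy0 + seq(-1, 1, by = 1 / upsample)
  v <- dx0 + seq(-1, 1, by = 1 / upsample)
  C <- Re(exp(2i * pi * outer(u, kr) / h) %*% cross %*%
            t(exp(2i * pi * outer(v, kc) / w)))
  mx <- which(C == max(C), arr.ind = TRUE)[1, ]
  structure(c(dx = v[mx[2]], dy = u[mx[1]]), psr = psr)
}

hann2d <- function(h, w) {
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(h) - 1) / (h - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(w) - 1) / (w - 1))
  outer(wr, wc)
}

#' Shift an image by an integer number of pixels
#'
#' Utility for tests and demonstrations: shifts content by `(dx, dy)` px
#' (columns rightward, rows downward), filling vacated pixels with the image
#' mean. The shifted copy of `img` is what [measure_displacement()] reports
#' as `(dx, dy)` relative to the original.
#' @param img 2D matrix.
#' @param dx,dy Integer shifts in px.
#' @export
shift_image <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(mean(img), h, w)
  sr <- seq_len(h) - dy; sc <- seq_len(w) - dx
  ok_r <- sr >= 1 & sr <= h; ok_c <- sc >= 1 & sc <= w
  out[which(ok_r), which(ok_c)] <- img[sr[ok_r], sc[ok_c]]
  out
}
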