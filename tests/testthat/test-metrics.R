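# brute-force 4-neighbour Laplacian over the interior, the independent
# oracle for laplacian_sharpness
laplacian_oracle <- function(m) {
  h <- nrow(m); w <- ncol(m)
  acc <- 0
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    l <- m[i - 1, j] + m[i + 1, j] + m[i, j - 1] + m[i, j + 1] - 4 * m[i, j]
    acc <- acc + l^4
  }
  acc
}

test_that("greyscale conversion uses convex BT.601 weights", {
  px <- array(0.4, dim = c(8, 8, 3))
  expect_equal(to_grayscale(px), matrix(0.4, 8, 8))

  red <- array(0, dim = c(8, 8, 3)); red[, , 1] <- 1
  expect_equal(to_grayscale(red), matrix(0.299, 8, 8))
  green <- array(0, dim = c(8, 8, 3)); green[, , 2] <- 1
  expect_equal(to_grayscale(green), matrix(0.587, 8, 8))

  set.seed(1)
  rnd <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  g <- to_grayscale(rnd)
  expect_true(all(g >= 0 & g <= 1))

  expect_error(to_grayscale(matrix(0, 4, 4)), "3-channel")
})

test_that("laplacian sharpness matches the hand-computed impulse value", {
  m <- matrix(0, 7, 7); m[4, 4] <- 1
  expect_equal(laplacian_sharpness(m), 260)   # (-4)^4 + 4 * 1^4
  expect_equal(laplacian_oracle(m), 260)
})

test_that("laplacian sharpness equals the brute-force oracle on random images", {
  set.seed(3)
  for (k in 1:5) {
    m <- matrix(runif(15 * 12), 15, 12)
    expect_equal(laplacian_sharpness(m), laplacian_oracle(m))
  }
})

test_that("laplacian sharpness invariances hold", {
  set.seed(4)
  m <- matrix(runif(20 * 20), 20, 20)
  expect_equal(laplacian_sharpness(matrix(0.7, 10, 10)), 0)
  expect_equal(laplacian_sharpness(m + 0.3), laplacian_sharpness(m),
               tolerance = 1e-9)
  for (s in c(0, 0.5, 2)) {
    expect_equal(laplacian_sharpness(s * m), s^4 * laplacian_sharpness(m),
                 tolerance = 1e-9)
  }
  chk <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  blur <- (chk + chk[c(2:16, 16), ] + chk[c(1, 1:15), ] +
           chk[, c(2:16, 16)] + chk[, c(1, 1:15)]) / 5
  expect_gt(laplacian_sharpness(chk), laplacian_sharpness(blur))
  expect_error(laplacian_sharpness(matrix(0, 2, 5)), "3x3")
})

test_that("displacement of identical frames is zero", {
  g <- test_scope(seed = 8)$grab_gray()
  d <- measure_displacement(g, g)
  expect_lt(max(abs(d)), 0.05)
})

test_that("integer shifts are recovered to within 0.1 px", {
  g <- test_scope(seed = 8)$grab_gray()
  for (sh in list(c(5, -3), c(-12, 7), c(0, 9))) {
    d <- measure_displacement(g, shift_image(g, sh[1], sh[2]))
    expect_lt(max(abs(d - sh)), 0.1)
  }
})

test_that("displacement measurement is antisymmetric", {
  sc <- test_scope(seed = 9)
  set.seed(10)
  for (k in 1:4) {
    sc$move_to(c(0, 0, sc$camera$z_focus))
    a <- sc$grab_gray()
    sc$move_to(c(round(runif(1, -25, 25)), round(runif(1, -25, 25)),
                 sc$camera$z_focus))
    b <- sc$grab_gray()
    dab <- measure_displacement(a, b)
    dba <- measure_displacement(b, a)
    expect_lt(max(abs(dab + dba)), 0.1)
  }
})

test_that("sub-pixel shifts up to a quarter frame are measured within 0.2 px", {
  # 0.7 px/step affine turns integer steps into fractional pixel shifts
  sc <- test_scope(density = 0.3, seed = 11, true_affine = diag(2) * 0.7)
  set.seed(12)
  for (k in 1:5) {
    sc$move_to(c(0, 0, sc$camera$z_focus))
    a <- sc$grab_gray()
    step <- round(runif(2, -40, 40))
    sc$move_to(c(step, sc$camera$z_focus))
    b <- sc$grab_gray()
    d <- measure_displacement(a, b)
    expect_lt(max(abs(d - 0.7 * step)), 0.2)
  }
})

test_that("featureless frames raise a low-confidence error with a diagnostic", {
  blank <- matrix(0.5, 64, 64)
  err <- expect_error_class(measure_displacement(blank, blank),
                            "vs_low_confidence")
  expect_true(is.numeric(err$psr))
  expect_error(measure_displacement(matrix(0, 4, 4), matrix(0, 5, 5)),
               "identical shape")
})
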