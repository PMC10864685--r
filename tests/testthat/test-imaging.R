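test_that("grayscale conversion applies Rec.601 luma weights", {
  arr <- array(0, dim = c(2, 2, 3))
  arr[1, 1, ] <- c(0.5, 0.5, 0.5)
  arr[1, 2, ] <- c(1, 0, 0)
  arr[2, 1, ] <- c(0, 1, 0)
  arr[2, 2, ] <- c(0, 0, 1)
  g <- to_grayscale(arr)
  expect_equal(g[1, 1], 0.5)
  expect_equal(g[1, 2], 0.299)
  expect_equal(g[2, 1], 0.587)
  expect_equal(g[2, 2], 0.114)
  expect_equal(to_grayscale(array(0, dim = c(2, 2, 3)))[1, 1], 0)

  expect_error(to_grayscale(matrix(0, 2, 2)), class = "scutematch_invalid_input")
  expect_error(to_grayscale(array(0, dim = c(2, 2, 4))),
               class = "scutematch_invalid_input")
})

test_that("gray_image enforces the intensity range invariant", {
  expect_error(gray_image(matrix(-0.1, 3, 3)), class = "scutematch_invalid_input")
  expect_error(gray_image(matrix(1.1, 3, 3)), class = "scutematch_invalid_input")
  img <- gray_image(matrix(0.5, 4, 6))
  expect_equal(image_width(img), 6)
  expect_equal(image_height(img), 4)
})

test_that("elliptical crop matches the per-pixel membership oracle", {
  img <- gray_image(matrix(1, 100, 100))
  roi <- ellipse_roi(49.5, 49.5, 50, 25)
  out <- crop_ellipse(img, roi)
  # independent brute-force membership count
  n_inside <- 0L
  for (x in 0:99) for (y in 0:99) {
    if ((x - 49.5)^2 / 50^2 + (y - 49.5)^2 / 25^2 <= 1) n_inside <- n_inside + 1L
  }
  expect_equal(sum(out > 0), n_inside)
})

test_that("elliptical crop preserves pixels and rejects degenerate axes", {
  img <- gray_image(matrix(runif(30 * 40, 0.1, 1), 30, 40))
  big <- ellipse_roi((40 - 1) / 2, (30 - 1) / 2, 200, 200)
  out <- crop_ellipse(img, big)
  expect_equal(unclass(out), unclass(img), ignore_attr = TRUE)

  expect_error(ellipse_roi(10, 10, 0, 5), class = "scutematch_invalid_input")
  expect_error(crop_ellipse(img, ellipse_roi(500, 500, 3, 3)),
               class = "scutematch_invalid_input")
})

test_that("rotated elliptical crop zeroes pixels outside the ellipse", {
  img <- gray_image(matrix(1, 60, 60))
  out <- crop_ellipse(img, ellipse_roi(29.5, 29.5, 25, 10, rotation = 30))
  expect_true(sum(out > 0) > 0)
  expect_true(sum(out > 0) < length(out))
  # area of an ellipse is invariant to its rotation
  out0 <- crop_ellipse(img, ellipse_roi(29.5, 29.5, 25, 10))
  expect_lt(abs(sum(out > 0) - sum(out0 > 0)) / sum(out0 > 0), 0.02)
})

test_that("identity enhancement returns the input bit-exactly", {
  img <- gray_image(matrix(runif(64 * 48), 48, 64))
  out <- enhance(img, enhance_params())
  expect_identical(unclass(out)[, ], unclass(img)[, ])
})

test_that("enhancement stages follow their closed forms", {
  u <- gray_image(matrix(0.25, 20, 20))
  g <- enhance(u, enhance_params(gamma = 2))
  expect_equal(unique(as.vector(unclass(g))), 0.25^0.5)

  sharp <- enhance(u, enhance_params(sharpen_amount = 2.5))
  expect_equal(unclass(sharp)[, ], unclass(u)[, ], tolerance = 1e-12)

  ramp <- gray_image(matrix(seq(0, 1, length.out = 32), 32, 32))
  st <- enhance(ramp, enhance_params(contrast = 100))
  expect_equal(min(st), 0)
  expect_equal(max(st), 1)

  gain <- enhance(gray_image(matrix(0.2, 5, 5)), enhance_params(exposure_gain = 3))
  expect_equal(unique(as.vector(unclass(gain))), 0.6)
})

test_that("enhancement parameters are validated at construction", {
  expect_error(enhance_params(gamma = 0), class = "scutematch_invalid_input")
  expect_error(enhance_params(exposure_gain = 0.5),
               class = "scutematch_invalid_input")
  expect_error(enhance_params(contrast = 150),
               class = "scutematch_invalid_input")
})

test_that("grayscale and enhancement commute with horizontal flip", {
  flip <- function(m) m[, ncol(m):1, drop = FALSE]
  arr <- array(runif(24 * 32 * 3), dim = c(24, 32, 3))
  arr_f <- arr[, 32:1, , drop = FALSE]
  expect_equal(flip(unclass(to_grayscale(arr))), unclass(to_grayscale(arr_f))[, ])

  params <- enhance_params(sharpen_amount = 1.5, exposure_gain = 2,
                           contrast = 40, gamma = 1.8, lightness_offset = -10)
  img <- gray_image(matrix(runif(48 * 64), 48, 64))
  left <- flip(unclass(enhance(img, params)))
  right <- unclass(enhance(gray_image(flip(unclass(img))), params))
  expect_equal(left, right[, ], tolerance = 1e-12)
})

test_that("bilinear resize hits exact targets and interpolates correctly", {
  img <- gray_image(matrix(runif(889 %/% 4 * (1330 %/% 4)), 889 %/% 4, 1330 %/% 4))
  out <- resize_working(img, 640, 480)
  expect_equal(dim(out), c(480, 640))

  same <- gray_image(matrix(runif(480 * 640), 480, 640))
  expect_equal(unclass(resize_working(same, 640, 480))[, ], unclass(same)[, ])

  tiny <- gray_image(matrix(c(0, 1, 0.5, 0.25), 2, 2))
  up <- resize_working(tiny, 3, 3)
  expect_equal(up[2, 2], mean(c(0, 1, 0.5, 0.25)))
  expect_equal(up[1, 1], tiny[1, 1])
  expect_equal(up[3, 3], tiny[2, 2])

  expect_error(resize_working(tiny, 2, 10), class = "scutematch_invalid_input")
})
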