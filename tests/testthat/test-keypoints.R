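test_that("gradient formula reproduces hand-computed cases", {
  # 3-4-5 triangle: dx = 3, dy = 4
  L <- matrix(0, 3, 3)
  L[2, 3] <- 1.5; L[2, 1] <- -1.5   # L(x+1,y) - L(x-1,y) = 3
  L[3, 2] <- 2; L[1, 2] <- -2       # L(x,y+1) - L(x,y-1) = 4
  g <- gradient_at(L, 1, 1)
  expect_equal(g$magnitude, 5)
  expect_equal(g$orientation, atan2(4, 3) * 180 / pi, tolerance = 1e-9)
  expect_equal(g$orientation, 53.130, tolerance = 1e-3)

  # flat patch: zero magnitude, orientation 0 by convention
  gf <- gradient_at(matrix(0.5, 3, 3), 1, 1)
  expect_equal(gf$magnitude, 0)
  expect_equal(gf$orientation, 0)

  # dx = -1, dy = 0 points along -x
  L2 <- matrix(0, 3, 3)
  L2[2, 3] <- -0.5; L2[2, 1] <- 0.5
  g2 <- gradient_at(L2, 1, 1)
  expect_equal(g2$magnitude, 1)
  expect_equal(g2$orientation, 180)

  expect_error(gradient_at(matrix(0, 3, 3), 0, 1),
               class = "scutematch_invalid_input")
})

test_that("edge response separates corners from edges at r = 10", {
  bound <- (10 + 1)^2 / 10  # 12.1
  expect_equal(edge_response(10, 10, 0), 4)
  expect_lt(edge_response(10, 10, 0), bound)
  expect_equal(edge_response(100, 1, 0), 102.01)
  expect_gte(edge_response(100, 1, 0), bound)
  expect_equal(edge_response(1, -1, 0), Inf)
})

test_that("refinement rejects low contrast and keeps strong blobs", {
  cfg <- sift_config()
  cand <- list(octave = 1L, level = 2L, x = 10L, y = 10L)

  weak <- refine_candidate(cand, blob_dog(0.01), cfg)
  expect_false(weak$accepted)
  expect_equal(weak$reason, "low_contrast")

  strong <- refine_candidate(cand, blob_dog(0.2), cfg)
  expect_true(strong$accepted)
  expect_gte(abs(strong$keypoint$response), cfg$contrast_threshold)
  # isotropic blob: sub-pixel offset stays at the centre
  expect_equal(strong$keypoint$x, 10, tolerance = 0.51)
  expect_equal(strong$keypoint$y, 10, tolerance = 0.51)
})

test_that("orientation assignment finds ramp and two-population peaks", {
  cfg <- sift_config()

  # horizontal ramp: all gradients point +x, orientation within half a bin
  ramp <- outer(rep(1, 33), seq_len(33)) * 0.01
  pyr <- patch_pyramid(ramp)
  kp <- patch_keypoint(ramp)
  out <- assign_orientations(kp, pyr, cfg)
  expect_equal(nrow(out), 1)
  ang <- out$orientation
  expect_lte(min(ang, 360 - ang), 5 + 1e-6)

  # L = max(row, col): gradient +x above the diagonal, +y below, value-
  # continuous, so the window holds two equal orthogonal populations
  n <- 41
  two <- 0.01 * outer(seq_len(n), seq_len(n), pmax)
  pyr2 <- patch_pyramid(two)
  out2 <- assign_orientations(patch_keypoint(two), pyr2, cfg)
  expect_equal(nrow(out2), 2)
  angs <- sort(out2$orientation)
  expect_equal(angs[1], 5, tolerance = 6)
  expect_equal(angs[2], 92, tolerance = 8)

  # constant patch: keypoint discarded
  flat <- matrix(0.5, 33, 33)
  out3 <- assign_orientations(patch_keypoint(flat), patch_pyramid(flat), cfg)
  expect_equal(nrow(out3), 0)
})

test_that("descriptors have length 128, unit norm, and clamped entries", {
  cfg <- sift_config()
  fs <- working_features(21)
  expect_gt(nrow(fs$keypoints), 50)
  expect_equal(ncol(fs$descriptors), 128)
  norms <- sqrt(rowSums(fs$descriptors^2))
  expect_true(all(abs(norms - 1) < 1e-6))
  expect_true(all(fs$descriptors <= cfg$descriptor_clamp + 1e-6))
  expect_true(all(fs$descriptors >= 0))
})

test_that("feature extraction is deterministic and handles flat images", {
  expect_warning(fs0 <- extract_features(constant_image()), "No keypoints")
  expect_equal(nrow(fs0$keypoints), 0)
  expect_equal(nrow(fs0$descriptors), 0)

  img <- resize_working(working_pattern(31), 320, 240)
  a <- extract_features(img, image_id = "a")
  b <- extract_features(img, image_id = "a")
  expect_identical(a$keypoints, b$keypoints)
  expect_identical(a$descriptors, b$descriptors)

  # keypoints live inside the working frame
  expect_true(all(a$keypoints$x >= 0 & a$keypoints$x < 320))
  expect_true(all(a$keypoints$y >= 0 & a$keypoints$y < 240))
  expect_true(all(abs(a$keypoints$response) >= sift_config()$contrast_threshold))
})
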