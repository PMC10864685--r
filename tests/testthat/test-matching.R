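test_that("knn search is exact against a brute-force distance scan", {
  for (seed in 1:5) {
    set.seed(seed)
    q <- matrix(runif(50 * 128), 50, 128)
    t <- matrix(runif(80 * 128), 80, 128)
    nn <- knn_search(q, t, k = 2)
    want <- brute_force_knn(q, t, 2)
    got <- matrix(nn$distance, ncol = 2, byrow = TRUE)
    expect_equal(got, want, tolerance = 1e-9, ignore_attr = TRUE)
    # distances sorted ascending per query
    expect_true(all(got[, 1] <= got[, 2]))
  }
})

test_that("knn search handles exact hits and undersized targets", {
  t <- matrix(runif(10 * 16), 10, 16)
  nn <- knn_search(t[3, , drop = FALSE], t, k = 2)
  expect_lt(nn$distance[nn$rank == 1], 1e-6)
  expect_equal(nn$target[nn$rank == 1], 3)

  small <- knn_search(matrix(runif(2 * 16), 2, 16),
                      matrix(runif(16), 1, 16), k = 2)
  expect_true(all(small$unmatched))
})

test_that("ratio test accepts strictly and rejects degenerate distances", {
  mk <- function(d1, d2) {
    tibble::tibble(query = c(1L, 1L), rank = c(1L, 2L), target = c(1L, 2L),
                   distance = c(d1, d2), unmatched = FALSE)
  }
  expect_equal(nrow(ratio_filter(mk(0.5, 1))), 1)
  expect_equal(nrow(ratio_filter(mk(0.75, 1))), 0)   # strict inequality
  expect_equal(nrow(ratio_filter(mk(0, 0))), 0)      # duplicate descriptors
  expect_equal(nrow(ratio_filter(mk(0, 1))), 1)
})

test_that("match count is invariant to target descriptor permutation", {
  fa <- working_features(41)
  fb <- working_features(43)
  m1 <- match_images(fa, fb)
  set.seed(9)
  perm <- sample(nrow(fb$descriptors))
  fb_perm <- feature_set(fb$image_id, fb$individual_id, fb$group,
                         fb$keypoints[perm, ], fb$descriptors[perm, ],
                         fb$config)
  m2 <- match_images(fa, fb_perm)
  expect_equal(m1$n_matches, m2$n_matches)
})

test_that("raising the ratio threshold never decreases the match count", {
  fa <- working_features(41)
  fb <- working_features(43)
  counts <- vapply(c(0.5, 0.65, 0.75, 0.85, 0.95), function(th) {
    match_images(fa, fb, match_config(ratio_threshold = th))$n_matches
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("self-matching excludes the zero-distance neighbour", {
  # 10-descriptor fixture with a brute-force oracle
  set.seed(5)
  d <- matrix(runif(10 * 8), 10, 8)
  fs <- feature_set("self", "i1", "close",
                    tibble::tibble(x = runif(10), y = runif(10),
                                   octave = 1L, level = 1L, sigma = 1.6,
                                   response = 0.1, orientation = 0),
                    d, sift_config())
  m <- match_images(fs, fs)
  # oracle: for each query, nearest/second-nearest among the other 9
  expected <- 0L
  for (i in 1:10) {
    dist <- sqrt(colSums((t(d[-i, , drop = FALSE]) - d[i, ])^2))
    s <- sort(dist)
    if (s[2] > 0 && s[1] < 0.75 * s[2]) expected <- expected + 1L
  }
  expect_equal(m$n_matches, expected)
})

test_that("matching empty feature sets yields zero matches", {
  empty <- suppressWarnings(extract_features(constant_image(), image_id = "e"))
  full <- working_features(41)
  expect_equal(match_images(empty, full)$n_matches, 0)
  expect_equal(match_images(full, empty)$n_matches, 0)
})

test_that("same-individual views outmatch different individuals", {
  A <- working_pattern(41)
  fa <- working_features(41)
  fb <- working_features(43)
  v <- render_view(A, transform_params(rotation = 10, scale = 1.05,
                                       blur_sigma = 0.7, noise_sd = 0.01),
                   view_seed = 3)
  fv <- extract_features(v, image_id = "view")
  same <- match_images(fv, fa)$n_matches
  diff <- match_images(fv, fb)$n_matches
  expect_gt(same, 5 * diff)
})

test_that("identification predicts the argmax individual deterministically", {
  fa <- working_features(41)
  fb <- working_features(43)
  fc <- working_features(47)
  db <- feature_db(list(fa, fb, fc))

  # the query is itself in the database
  res <- identify(fa, db)
  expect_equal(res$predicted_individual, fa$individual_id)
  expect_equal(res$best_image_id, fa$image_id)
  expect_equal(nrow(res$scores), 3)

  res2 <- identify(fa, db)
  expect_identical(glance(res), glance(res2))
})

test_that("batched identification scores equal pairwise image matching", {
  query <- working_features(47)
  db <- feature_db(list(working_features(41), working_features(43)))
  res <- identify(query, db)
  direct <- vapply(db$entries, function(e) {
    match_images(query, e)$n_matches
  }, numeric(1))
  expect_equal(res$scores$n_matches, as.integer(direct))
})

test_that("all-zero scores with a minimum match count predict none", {
  empty <- suppressWarnings(extract_features(constant_image(), image_id = "q"))
  db <- feature_db(list(working_features(41), working_features(43)))
  res <- identify(empty, db, match_config(min_match_count = 1))
  expect_true(is.na(res$predicted_individual))
  expect_true(res$tie_broken)
  expect_error(identify(empty, list()), class = "scutematch_invalid_input")
})
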