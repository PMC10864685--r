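test_that("pattern generation is seed-deterministic and distinct by seed", {
  s <- small_spec(3)
  a <- make_pattern(s)
  b <- make_pattern(s)
  expect_identical(unclass(a), unclass(b))

  # distinctness over seed pairs: mean abs difference where both patterns
  # have content
  for (seed in c(1, 5, 9)) {
    p1 <- make_pattern(small_spec(seed))
    p2 <- make_pattern(small_spec(seed + 1000))
    joint <- p1 > 0 & p2 > 0
    expect_gt(mean(abs(p1[joint] - p2[joint])), 0.01)
  }
})

test_that("degenerate pattern parameters give a uniform masked disc", {
  s <- pattern_spec(7, n_cells = 50, boundary_darkness = 1e-9,
                    cell_shade_sd = 0, width = 200, height = 150)
  p <- make_pattern(s)
  inside <- p > 0
  expect_gt(sum(inside), 0)
  expect_lt(diff(range(p[inside])), 1e-6)
})

test_that("pattern spec validates its invariants", {
  expect_error(pattern_spec(1, n_cells = 5), class = "scutematch_invalid_input")
  expect_error(pattern_spec(1, boundary_darkness = 1.5),
               class = "scutematch_invalid_input")
  expect_error(transform_params(scale = 0), class = "scutematch_invalid_input")
  expect_error(transform_params(noise_sd = -1),
               class = "scutematch_invalid_input")
})

test_that("view rendering is deterministic with identity passthrough", {
  p <- make_pattern(small_spec(11))
  expect_identical(unclass(render_view(p, transform_params(), 1)),
                   unclass(p))

  t <- transform_params(rotation = 8, gain = 0.9, blur_sigma = 1,
                        noise_sd = 0.02)
  v1 <- render_view(p, t, view_seed = 99)
  v2 <- render_view(p, t, view_seed = 99)
  expect_identical(unclass(v1), unclass(v2))
  v3 <- render_view(p, t, view_seed = 100)
  expect_false(identical(unclass(v1), unclass(v3)))
})

test_that("a full turn returns the pattern up to interpolation error", {
  p <- make_pattern(small_spec(13))
  back <- render_view(p, transform_params(rotation = 360), 1)
  expect_lt(mean(abs(unclass(back) - unclass(p))), 0.02)
})

test_that("far-tier renders are darker and less detailed than close-tier", {
  tr <- default_transform_ranges()
  for (seed in c(2, 4, 6)) {
    p <- make_pattern(small_spec(seed))
    close <- render_view(p, transform_params(
      blur_sigma = mean(tr$close$blur_sigma), noise_sd = 0,
      gain = mean(tr$close$gain)), 1)
    far <- render_view(p, transform_params(
      blur_sigma = mean(tr$far$blur_sigma), noise_sd = 0,
      gain = mean(tr$far$gain), tier = "far"), 1)
    expect_lt(mean_gradient(far), mean_gradient(close))
    expect_lt(mean(far), mean(close))
  }
})

test_that("benchmark datasets have the contracted shape and determinism", {
  b1 <- make_benchmark(n_individuals = 3, images_per_individual = 3,
                       global_seed = 7,
                       pattern_defaults = list(width = 200, height = 150))
  expect_equal(nrow(b1$manifest), 9)
  expect_length(b1$images, 9)
  expect_equal(length(unique(b1$manifest$individual_id)), 3)
  expect_true(all(table(b1$manifest$individual_id) == 3))

  b2 <- make_benchmark(n_individuals = 3, images_per_individual = 3,
                       global_seed = 7,
                       pattern_defaults = list(width = 200, height = 150))
  expect_identical(b1$manifest, b2$manifest)
  expect_identical(lapply(b1$images, unclass), lapply(b2$images, unclass))

  expect_error(make_benchmark(n_individuals = 1),
               class = "scutematch_invalid_input")
})

test_that("within-individual distances fall below between-individual ones", {
  b <- make_benchmark(n_individuals = 4, images_per_individual = 2,
                      global_seed = 11,
                      pattern_defaults = list(width = 200, height = 150))
  imgs <- lapply(b$images, unclass)
  man <- b$manifest
  d <- function(i, j) mean(abs(imgs[[i]] - imgs[[j]]))
  within <- c(); between <- c()
  for (i in seq_len(nrow(man) - 1)) {
    for (j in (i + 1):nrow(man)) {
      if (man$individual_id[i] == man$individual_id[j]) {
        within <- c(within, d(i, j))
      } else {
        between <- c(between, d(i, j))
      }
    }
  }
  expect_gt(mean(between), mean(within))
})
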