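# Shared fixtures, built in code and memoised for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Heterogeneous pattern spec at working-canvas size, mirroring the
# between-individual variation the benchmark generator draws.
working_spec <- function(seed, width = 640, height = 480) {
  d <- withr::with_seed(seed + 1L, list(
    n_cells = round(runif(1, 300, 550)),
    ax = runif(1, 0.42, 0.48),
    ay = runif(1, 0.38, 0.46)))
  pattern_spec(seed, n_cells = d$n_cells, boundary_width = 2.5,
               width = width, height = height,
               ellipse_ax = d$ax, ellipse_ay = d$ay)
}

working_pattern <- function(seed, ...) {
  cached(paste0("pattern_", seed), make_pattern(working_spec(seed, ...)))
}

working_features <- function(seed) {
  cached(paste0("features_", seed),
         extract_features(working_pattern(seed),
                          image_id = paste0("img", seed),
                          individual_id = paste0("ind", seed)))
}

# Small pattern (fast to extract) for bulk property sweeps.
small_spec <- function(seed) {
  d <- withr::with_seed(seed + 1L, list(
    n_cells = round(runif(1, 60, 110)),
    ax = runif(1, 0.42, 0.48),
    ay = runif(1, 0.38, 0.46)))
  pattern_spec(seed, n_cells = d$n_cells, boundary_width = 2,
               width = 256, height = 192,
               ellipse_ax = d$ax, ellipse_ay = d$ay)
}

# A flat-gray constant image.
constant_image <- function(value = 0.5, width = 64, height = 64) {
  gray_image(matrix(value, height, width))
}

# Hand-crafted DoG pyramid holding a single isotropic blob of amplitude
# `amp` in the middle level; used to exercise refinement in isolation.
blob_dog <- function(amp, n = 21, width_scale = 4) {
  ctr <- (n + 1) / 2
  g <- outer(seq_len(n), seq_len(n), function(r, c) {
    amp * exp(-((r - ctr)^2 + (c - ctr)^2) / (2 * width_scale))
  })
  mid <- g
  side <- 0.5 * g
  structure(
    list(octaves = list(list(images = list(side, mid, side, side * 0.25),
                             sigma_rel = 1.6 * sqrt(2)^(0:3))),
         cfg = sift_config(), width = n, height = n),
    class = "dog_pyramid"
  )
}

# One-octave, one-level Gaussian "pyramid" wrapping a given matrix, with a
# keypoint at its centre; exercises orientation/descriptor in isolation.
patch_pyramid <- function(L, sigma = 1.6) {
  structure(
    list(octaves = list(list(images = list(L),
                             sigma_rel = sigma, sigma_abs = sigma)),
         cfg = sift_config(), width = ncol(L), height = nrow(L)),
    class = "gaussian_pyramid"
  )
}

patch_keypoint <- function(L, sigma = 1.6) {
  ctr_x <- (ncol(L) - 1) / 2
  ctr_y <- (nrow(L) - 1) / 2
  tibble::tibble(x = ctr_x, y = ctr_y, octave = 1L, level = 1L,
                 gauss_level = 1L, sigma = sigma, response = 1,
                 x_oct = ctr_x, y_oct = ctr_y)
}

# Brute-force 26-neighbour extrema scan, independent of the package path.
brute_force_extrema <- function(dog) {
  out <- list()
  for (o in seq_along(dog$octaves)) {
    D <- dog$octaves[[o]]$images
    nlev <- length(D)
    nr <- nrow(D[[1]]); nc <- ncol(D[[1]])
    for (l in 2:(nlev - 1)) {
      for (r in 2:(nr - 1)) {
        for (cc in 2:(nc - 1)) {
          v <- D[[l]][r, cc]
          nb <- c(D[[l - 1]][(r - 1):(r + 1), (cc - 1):(cc + 1)],
                  D[[l]][(r - 1):(r + 1), (cc - 1):(cc + 1)],
                  D[[l + 1]][(r - 1):(r + 1), (cc - 1):(cc + 1)])
          others <- nb[-14]  # centre of the 27-cell block
          if (v > max(others) || v < min(others)) {
            out[[length(out) + 1]] <-
              data.frame(octave = o, level = l, x = cc - 1, y = r - 1)
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(octave = integer(), level = integer(),
                      x = integer(), y = integer()))
  }
  do.call(rbind, out)
}

# Brute-force exact kNN by full distance matrix.
brute_force_knn <- function(query, target, k) {
  t(apply(query, 1, function(q) {
    d <- sqrt(colSums((t(target) - q)^2))
    sort(d)[seq_len(k)]
  }))
}
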