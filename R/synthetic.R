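#' Synthetic scale-pattern specification
#'
#' Describes one individual's tessellated scale pattern: a jittered-grid
#' Voronoi mosaic (each cell a "scute") with per-cell shading, darkened
#' cell boundaries, and an elliptical silhouette mask. The pattern is a
#' deterministic function of `individual_seed`.
#'
#' @param individual_seed Integer seed; two individuals differ only here.
#' @param n_cells Approximate number of scale cells (>= 10).
#' @param cell_jitter Seed-point jitter as a fraction of the mean cell
#'   spacing, in \[0, 0.5\].
#' @param boundary_width Width in pixels over which cell boundaries darken.
#' @param boundary_darkness Intensity drop at a cell boundary, in (0, 1\].
#' @param cell_shade_sd Standard deviation of per-cell shading.
#' @param width,height Canvas size in pixels (defaults mirror the
#'   1330 x 889 originals of the reference workflow).
#' @param ellipse_ax,ellipse_ay Silhouette semi-axes as fractions of the
#'   canvas width and height; tails differ in outline, so
#'   [make_benchmark()] varies these per individual.
#' @return A `pattern_spec` object.
#' @export
pattern_spec <- function(individual_seed, n_cells = 400, cell_jitter = 0.45,
                         boundary_width = 5, boundary_darkness = 0.45,
                         cell_shade_sd = 0.12, width = 1330, height = 889,
                         ellipse_ax = 0.48, ellipse_ay = 0.46) {
  if (n_cells < 10) abort("`n_cells` must be >= 10.",
                          class = "scutematch_invalid_input")
  if (boundary_darkness <= 0 || boundary_darkness > 1) {
    abort("`boundary_darkness` must lie in (0, 1].",
          class = "scutematch_invalid_input")
  }
  structure(list(individual_seed = as.integer(individual_seed),
                 n_cells = n_cells, cell_jitter = cell_jitter,
                 boundary_width = boundary_width,
                 boundary_darkness = boundary_darkness,
                 cell_shade_sd = cell_shade_sd,
                 width = as.integer(width), height = as.integer(height),
                 ellipse_ax = ellipse_ax, ellipse_ay = ellipse_ay),
            class = "pattern_spec")
}

#' Render an individual's scale pattern
#'
#' Rasterizes the jittered-grid Voronoi mosaic of a [pattern_spec()]:
#' seed points on a regular grid perturbed by uniform jitter, each cell
#' filled with a base intensity plus Gaussian shading, boundaries darkened
#' by `boundary_darkness` over `boundary_width` pixels, and an elliptical
#' tail-silhouette mask (pixels outside set to 0).
#'
#' @param spec A [pattern_spec()].
#' @return A [gray_image()] of the spec's canvas size.
#' @export
make_pattern <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  w <- spec$width; h <- spec$height
  # grid of cells matching the canvas aspect ratio
  spacing <- sqrt(w * h / spec$n_cells)
  gx <- max(2L, as.integer(ceiling(w / spacing)))
  gy <- max(2L, as.integer(ceiling(h / spacing)))
  base_intensity <- 0.62
  withr::with_seed(spec$individual_seed, {
    cx <- rep((seq_len(gx) - 0.5) * spacing, times = gy)
    cy <- rep((seq_len(gy) - 0.5) * spacing, each = gx)
    jit <- spec$cell_jitter * spacing
    cx <- cx + runif(gx * gy, -jit, jit)
    cy <- cy + runif(gx * gy, -jit, jit)
    shade <- pmin(1, pmax(0, base_intensity +
                            rnorm(gx * gy, 0, spec$cell_shade_sd)))
    # individual-specific silhouette irregularity (tail outlines are not
    # perfect ellipses): low-order harmonic radial wobble
    wob_amp <- runif(3, 0.01, 0.035)
    wob_phase <- runif(3, 0, 2 * pi)
  })
  img <- .voronoi_pattern_cpp(h, w, cx, cy, shade, gx, gy, spacing,
                              spec$boundary_width, spec$boundary_darkness)
  # elliptical silhouette slightly inside the canvas
  xs <- seq_len(w) - 1; ys <- seq_len(h) - 1
  a <- spec$ellipse_ax * w; b <- spec$ellipse_ay * h
  u <- (xs - (w - 1) / 2) / a
  v <- (ys - (h - 1) / 2) / b
  rad <- sqrt(outer(v^2, u^2, `+`))
  phi <- atan2(outer(v, rep(1, w)), outer(rep(1, h), u))
  rim <- 1
  for (kh in 1:3) {
    rim <- rim + wob_amp[kh] * cos((kh + 1) * phi + wob_phase[kh])
  }
  img[rad > rim] <- 0
  as_gray(img)
}

#' Imaging-transform parameters for a synthetic view
#'
#' One photographic "sighting" of a pattern: geometric rotation and scale
#' change, an intensity map (gain, offset, gamma), Gaussian blur, and
#' additive Gaussian noise. The `far` tier mimics images taken from
#' greater height: stronger blur, more noise and lower gain (darker,
#' lower-detail renders) than the `close` tier.
#'
#' @param rotation Degrees.
#' @param scale Multiplier; must be > 0.
#' @param gain,offset,gamma Intensity map `out = (gain * in + offset)^(1/gamma)`.
#' @param blur_sigma Gaussian blur in pixels (0 = none).
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param tier `"close"` or `"far"` quality tier label.
#' @return A `transform_params` object.
#' @export
transform_params <- function(rotation = 0, scale = 1, gain = 1, offset = 0,
                             gamma = 1, blur_sigma = 0, noise_sd = 0,
                             tier = "close") {
  if (scale <= 0) abort("`scale` must be > 0.",
                        class = "scutematch_invalid_input")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.",
                          class = "scutematch_invalid_input")
  if (gamma <= 0) abort("`gamma` must be > 0.",
                        class = "scutematch_invalid_input")
  structure(list(rotation = rotation, scale = scale, gain = gain,
                 offset = offset, gamma = gamma, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, tier = tier),
            class = "transform_params")
}

#' Render a transformed view of a pattern
#'
#' Applies, in order: rotation, rescaling (both bilinear, about the image
#' centre, zeros outside), the intensity map, Gaussian blur, additive
#' Gaussian noise (deterministic in `view_seed`), and a final clip to
#' \[0, 1\].
#'
#' @param pattern A [gray_image()] from [make_pattern()].
#' @param t A [transform_params()].
#' @param view_seed Integer seed for the noise.
#' @return A [gray_image()] of the same size.
#' @export
render_view <- function(pattern, t = transform_params(), view_seed = 1) {
  stopifnot(inherits(t, "transform_params"))
  x <- unclass(as_gray(pattern))
  if (t$rotation != 0 || t$scale != 1) {
    x <- .affine_view_cpp(x, t$rotation, t$scale)
  }
  if (t$gain != 1 || t$offset != 0) {
    x <- clip01(t$gain * x + t$offset)
  }
  if (t$gamma != 1) x <- x^(1 / t$gamma)
  if (t$blur_sigma > 0) x <- .gauss_blur_cpp(x, t$blur_sigma)
  if (t$noise_sd > 0) {
    withr::with_seed(view_seed, {
      x <- x + matrix(rnorm(length(x), 0, t$noise_sd), nrow(x), ncol(x))
    })
  }
  as_gray(x)
}

#' Default transform ranges for benchmark views
#'
#' Views are drawn uniformly from these ranges: rotation within 15
#' degrees either way, scale 0.9-1.1, gain 0.8-1.2, gamma 0.8-1.25.
#' Blur and noise depend on the tier: close views get blur sigma 0.5-1
#' and noise sd 0.01; far views get blur sigma 1.5-2.5, noise sd 0.03 and
#' reduced gain (0.55-0.8), emulating darker, lower-detail images taken
#' from greater height.
#'
#' @return A list of ranges consumed by [make_benchmark()].
#' @export
default_transform_ranges <- function() {
  list(rotation = c(-15, 15), scale = c(0.9, 1.1), gain = c(0.8, 1.2),
       gamma = c(0.8, 1.25),
       close = list(blur_sigma = c(0.5, 1.0), noise_sd = 0.01,
                    gain = c(0.8, 1.2)),
       far = list(blur_sigma = c(1.5, 2.5), noise_sd = 0.03,
                  gain = c(0.55, 0.8)))
}

#' Generate a synthetic identification benchmark
#'
#' Emulates a marked population imaged repeatedly: each individual gets a
#' unique scale pattern (seed derived from `global_seed`) rendered
#' `images_per_individual` times under transforms drawn from
#' `transform_ranges`. The first view of each individual is near-frontal
#' (identity geometry with tier-level blur/noise), as reference sightings
#' are. Fully deterministic in `global_seed`.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param images_per_individual Views per individual (>= 2).
#' @param global_seed Master seed.
#' @param pattern_defaults A [pattern_spec()]-argument list overriding the
#'   pattern defaults (without `individual_seed`).
#' @param transform_ranges See [default_transform_ranges()].
#' @param tier `"close"` or `"far"`.
#' @param transforms_enabled Set `FALSE` to render every view with the
#'   identity transform (no rotation/scale/intensity change/noise).
#' @param dir If non-`NULL`, write PNG images and a `manifest.csv` there
#'   and store paths in the manifest.
#' @return A `synthetic_dataset`: list with `manifest` (tibble: image_id,
#'   individual_id, group, rotation, scale, gain, gamma, blur_sigma,
#'   noise_sd, and `path` when written), `images` (named list of
#'   [gray_image()]s, present when `dir` is `NULL`) and `global_seed`.
#' @export
make_benchmark <- function(n_individuals = 25, images_per_individual = 8,
                           global_seed = 42, pattern_defaults = list(),
                           transform_ranges = default_transform_ranges(),
                           tier = c("close", "far"),
                           transforms_enabled = TRUE, dir = NULL) {
  tier <- match.arg(tier)
  if (n_individuals < 2 || images_per_individual < 2) {
    abort("Need >= 2 individuals and >= 2 images each.",
          class = "scutematch_invalid_input")
  }
  tr <- transform_ranges
  tier_tr <- tr[[tier]]
  ind_seeds <- withr::with_seed(global_seed,
                                sample.int(2^30, n_individuals))
  view_seeds <- withr::with_seed(global_seed + 1,
                                 sample.int(2^30,
                                            n_individuals * images_per_individual))
  rows <- list()
  images <- list()
  k <- 0L
  for (i in seq_len(n_individuals)) {
    ind_id <- sprintf("ind%03d", i)
    # between-individual heterogeneity: tails differ in scale size and
    # outline, so cell count and silhouette axes vary per individual
    drawn <- withr::with_seed(ind_seeds[i] + 1L, list(
      n_cells = round(runif(1, 300, 550)),
      ellipse_ax = runif(1, 0.42, 0.48),
      ellipse_ay = runif(1, 0.38, 0.46)))
    args <- utils::modifyList(c(list(individual_seed = ind_seeds[i]), drawn),
                              pattern_defaults)
    spec <- do.call(pattern_spec, args)
    pattern <- make_pattern(spec)
    for (j in seq_len(images_per_individual)) {
      k <- k + 1L
      vseed <- view_seeds[k]
      if (!transforms_enabled) {
        t <- transform_params(tier = tier)
      } else if (j == 1) {
        t <- transform_params(
          blur_sigma = mean(tier_tr$blur_sigma),
          noise_sd = tier_tr$noise_sd, tier = tier)
      } else {
        draw <- withr::with_seed(vseed, {
          list(rotation = runif(1, tr$rotation[1], tr$rotation[2]),
               scale = runif(1, tr$scale[1], tr$scale[2]),
               gain = runif(1, tier_tr$gain[1], tier_tr$gain[2]),
               gamma = runif(1, tr$gamma[1], tr$gamma[2]),
               blur = runif(1, tier_tr$blur_sigma[1], tier_tr$blur_sigma[2]))
        })
        t <- transform_params(rotation = draw$rotation, scale = draw$scale,
                              gain = draw$gain, gamma = draw$gamma,
                              blur_sigma = draw$blur,
                              noise_sd = tier_tr$noise_sd, tier = tier)
      }
      img <- render_view(pattern, t, view_seed = vseed + 1L)
      image_id <- sprintf("%s_view%02d", ind_id, j)
      rows[[k]] <- tibble(image_id = image_id, individual_id = ind_id,
                          group = tier, rotation = t$rotation,
                          scale = t$scale, gain = t$gain, gamma = t$gamma,
                          blur_sigma = t$blur_sigma, noise_sd = t$noise_sd)
      images[[image_id]] <- img
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$image_path <- file.path(dir, paste0(manifest$image_id, ".png"))
    purrr::walk2(images[manifest$image_id], manifest$image_path, write_image)
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
    images <- NULL
  }
  structure(list(manifest = manifest, images = images,
                 global_seed = global_seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d images of %d individuals (seed %d)\n",
              nrow(x$manifest), length(unique(x$manifest$individual_id)),
              x$global_seed))
  invisible(x)
}

#' Mean gradient magnitude of an image
#'
#' Central-difference gradient magnitude averaged over interior pixels; a
#' simple sharpness/detail measure used to contrast close- and far-tier
#' renders.
#'
#' @param image A [gray_image()].
#' @return A single number.
#' @export
mean_gradient <- function(image) {
  .mean_gradient_cpp(unclass(as_gray(image)))
}
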