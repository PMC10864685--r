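#' Build the Gaussian scale-space pyramid
#'
#' Constructs `n_octaves` octaves of `n_scale_levels` progressively blurred
#' images. Level j (0-based) of octave o has absolute blur scale
#' `base_sigma * k_factor^j * 2^o`; blurs are realized by incremental 2-D
#' Gaussian convolution with reflected borders. Each octave's base is the
#' previous octave's level with twice the base sigma, downsampled by
#' taking every second pixel. Images too small for the requested octave
#' count get fewer octaves, with a warning.
#'
#' @param image A [gray_image()] at working resolution.
#' @param cfg A [sift_config()].
#' @return A `gaussian_pyramid`: a list with `octaves` (each a list of
#'   `images`, per-octave `sigma_rel` and absolute `sigma_abs`) and the
#'   configuration.
#' @export
build_scale_space <- function(image, cfg = sift_config()) {
  x <- unclass(as_gray(image))
  n_oct <- cfg$n_octaves
  min_side <- min(dim(x))
  while (n_oct > 1 && min_side < 2^(n_oct - 1) * 8) {
    n_oct <- n_oct - 1
  }
  if (n_oct < cfg$n_octaves) {
    warn(sprintf("Image %dx%d too small for %d octaves; using %d.",
                 ncol(x), nrow(x), cfg$n_octaves, n_oct))
  }
  nlev <- cfg$n_scale_levels
  sigma_rel <- cfg$base_sigma * cfg$k_factor^(0:(nlev - 1))
  # level whose relative sigma doubles the octave base; start of next octave
  j2 <- min(nlev, round(log(2) / log(cfg$k_factor)) + 1)

  octaves <- vector("list", n_oct)
  base <- x
  for (o in seq_len(n_oct)) {
    imgs <- vector("list", nlev)
    imgs[[1]] <- .gauss_blur_cpp(base, sigma_rel[1])
    for (j in 2:nlev) {
      sd <- sqrt(sigma_rel[j]^2 - sigma_rel[j - 1]^2)
      imgs[[j]] <- .gauss_blur_cpp(imgs[[j - 1]], sd)
    }
    octaves[[o]] <- list(images = imgs, sigma_rel = sigma_rel,
                         sigma_abs = sigma_rel * 2^(o - 1))
    if (o < n_oct) {
      b <- imgs[[j2]]
      base <- b[seq(1, nrow(b), by = 2), seq(1, ncol(b), by = 2), drop = FALSE]
    }
  }
  structure(list(octaves = octaves, cfg = cfg,
                 width = ncol(x), height = nrow(x)),
            class = "gaussian_pyramid")
}

#' @export
print.gaussian_pyramid <- function(x, ...) {
  cat(sprintf("<gaussian_pyramid> %d octaves x %d levels over %dx%d px\n",
              length(x$octaves), x$cfg$n_scale_levels, x$width, x$height))
  invisible(x)
}

#' Build the difference-of-Gaussians pyramid
#'
#' Adjacent-level differences (higher sigma minus lower sigma) within each
#' octave of a Gaussian pyramid: `n_scale_levels - 1` band-pass images per
#' octave.
#'
#' @param pyr A pyramid from [build_scale_space()].
#' @return A `dog_pyramid` mirroring the octave structure.
#' @export
build_dog <- function(pyr) {
  stopifnot(inherits(pyr, "gaussian_pyramid"))
  octaves <- lapply(pyr$octaves, function(oct) {
    n <- length(oct$images)
    list(images = lapply(seq_len(n - 1),
                         function(j) oct$images[[j + 1]] - oct$images[[j]]),
         sigma_rel = oct$sigma_rel[-n])
  })
  structure(list(octaves = octaves, cfg = pyr$cfg,
                 width = pyr$width, height = pyr$height),
            class = "dog_pyramid")
}

#' Detect scale-space extrema
#'
#' Scans each interior DoG level for pixels strictly greater than (or
#' strictly smaller than) all 26 neighbours: the 8 in-plane neighbours and
#' the 9 each in the adjacent lower and upper scales. Border pixels and
#' the outermost levels are excluded; plateaus (ties) yield no candidate.
#'
#' @param dog A [build_dog()] pyramid.
#' @return A tibble of candidates with columns `octave`, `level` (1-based
#'   DoG level), `x`, `y` (0-based pixel coordinates in that octave's
#'   grid) and `value` (the DoG response).
#' @export
detect_extrema <- function(dog) {
  stopifnot(inherits(dog, "dog_pyramid"))
  res <- purrr::map_dfr(seq_along(dog$octaves), function(o) {
    m <- .detect_extrema_cpp(dog$octaves[[o]]$images)
    if (nrow(m) == 0) return(NULL)
    vals <- vapply(seq_len(nrow(m)), function(i) {
      dog$octaves[[o]]$images[[m[i, 1]]][m[i, 2], m[i, 3]]
    }, numeric(1))
    tibble(octave = o, level = m[, 1], x = m[, 3] - 1L, y = m[, 2] - 1L,
           value = vals)
  })
  if (nrow(res) == 0) {
    res <- tibble(octave = integer(), level = integer(), x = integer(),
                  y = integer(), value = numeric())
  }
  res
}

#' Principal-curvature edge response
#'
#' The edge criterion on the 2 x 2 spatial Hessian of the DoG: a keypoint
#' lying on an edge has one large and one small principal curvature, so
#' `tr(H)^2 / det(H)` is large. With curvature-ratio bound r, points with
#' response >= (r+1)^2/r, or with non-positive determinant, are rejected.
#'
#' @param dxx,dyy,dxy Second derivatives of the DoG at the point.
#' @return The ratio `tr(H)^2 / det(H)` (`Inf` when det <= 0).
#' @examples
#' edge_response(10, 10, 0)   # 4: isotropic corner, kept for r = 10
#' edge_response(100, 1, 0)   # 102.01: edge-like, rejected for r = 10
#' @export
edge_response <- function(dxx, dyy, dxy) {
  det <- dxx * dyy - dxy^2
  if (det <= 0) return(Inf)
  (dxx + dyy)^2 / det
}

#' Refine a candidate extremum into a keypoint
#'
#' Fits a second-order Taylor expansion of the DoG around the candidate in
#' (x, y, scale), yielding a sub-pixel offset and interpolated response.
#' If the offset exceeds 0.5 in any dimension, the fit moves to the
#' neighbouring sample and retries (at most 5 iterations). Candidates are
#' rejected for low contrast (interpolated |D| below
#' `contrast_threshold`) or an edge-like 2 x 2 spatial Hessian (see
#' [edge_response()]).
#'
#' @param candidate A list or one-row data frame with `octave`, `level`,
#'   `x`, `y` as produced by [detect_extrema()].
#' @param dog A [build_dog()] pyramid.
#' @param cfg A [sift_config()].
#' @return A list with `accepted` (logical), `reason` (`NA` when accepted,
#'   otherwise one of `"low_contrast"`, `"edge"`, `"no_convergence"`,
#'   `"out_of_bounds"`, `"singular"`), and when accepted a one-row tibble
#'   `keypoint` with working-image coordinates `x`, `y`, `octave`,
#'   `level`, `gauss_level`, `sigma` (absolute) and `response`.
#' @export
refine_candidate <- function(candidate, dog, cfg = sift_config()) {
  o <- candidate$octave
  oc <- dog$octaves[[o]]
  D <- oc$images
  nlev <- length(D)
  nr <- nrow(D[[1]]); nc <- ncol(D[[1]])
  i <- candidate$level
  r <- candidate$y + 1L
  cc <- candidate$x + 1L

  rejected <- function(reason) list(accepted = FALSE, reason = reason)
  g <- off <- NULL; hxx <- hyy <- hxy <- v <- NULL
  converged <- FALSE
  for (iter in 1:5) {
    if (i < 2 || i > nlev - 1 || r < 2 || r > nr - 1 || cc < 2 || cc > nc - 1) {
      return(rejected("out_of_bounds"))
    }
    d0 <- D[[i]]; dm <- D[[i - 1]]; dp <- D[[i + 1]]
    v <- d0[r, cc]
    g <- c((d0[r, cc + 1] - d0[r, cc - 1]) / 2,
           (d0[r + 1, cc] - d0[r - 1, cc]) / 2,
           (dp[r, cc] - dm[r, cc]) / 2)
    hxx <- d0[r, cc + 1] + d0[r, cc - 1] - 2 * v
    hyy <- d0[r + 1, cc] + d0[r - 1, cc] - 2 * v
    hss <- dp[r, cc] + dm[r, cc] - 2 * v
    hxy <- (d0[r + 1, cc + 1] - d0[r + 1, cc - 1] -
            d0[r - 1, cc + 1] + d0[r - 1, cc - 1]) / 4
    hxs <- (dp[r, cc + 1] - dp[r, cc - 1] - dm[r, cc + 1] + dm[r, cc - 1]) / 4
    hys <- (dp[r + 1, cc] - dp[r - 1, cc] - dm[r + 1, cc] + dm[r - 1, cc]) / 4
    H <- matrix(c(hxx, hxy, hxs, hxy, hyy, hys, hxs, hys, hss), 3, 3)
    off <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(off)) return(rejected("singular"))
    if (all(abs(off) <= 0.5)) { converged <- TRUE; break }
    cc <- cc + as.integer(sign(off[1]) * (abs(off[1]) > 0.5))
    r  <- r  + as.integer(sign(off[2]) * (abs(off[2]) > 0.5))
    i  <- i  + as.integer(sign(off[3]) * (abs(off[3]) > 0.5))
  }
  if (!converged) return(rejected("no_convergence"))

  dhat <- v + 0.5 * sum(g * off)
  if (abs(dhat) < cfg$contrast_threshold) return(rejected("low_contrast"))
  edge_bound <- (cfg$edge_r + 1)^2 / cfg$edge_r
  if (edge_response(hxx, hyy, hxy) >= edge_bound) return(rejected("edge"))

  scale_mult <- 2^(o - 1)
  x_img <- (cc - 1 + off[1]) * scale_mult
  y_img <- (r - 1 + off[2]) * scale_mult
  if (x_img < 0 || x_img >= dog$width || y_img < 0 || y_img >= dog$height) {
    return(rejected("out_of_bounds"))
  }
  lvl <- (i - 1) + off[3]
  sigma <- cfg$base_sigma * cfg$k_factor^lvl * scale_mult
  gauss_level <- min(max(round(lvl), 0), cfg$n_scale_levels - 1) + 1L
  list(accepted = TRUE, reason = NA_character_,
       keypoint = tibble(
         x = x_img, y = y_img, octave = o, level = i,
         gauss_level = gauss_level, sigma = sigma, response = dhat,
         x_oct = cc - 1 + off[1], y_oct = r - 1 + off[2]))
}

#' Gradient magnitude and orientation at a pixel
#'
#' Central-difference gradient of a blurred level:
#' `m = sqrt((L(x+1,y) - L(x-1,y))^2 + (L(x,y+1) - L(x,y-1))^2)` and
#' `theta = atan2(L(x,y+1) - L(x,y-1), L(x+1,y) - L(x-1,y))` mapped to
#' \[0, 360) degrees. The y axis points down (row index increases
#' downward); orientation 0 points toward +x. A flat neighbourhood has
#' magnitude 0 and orientation 0 by convention.
#'
#' @param L A numeric matrix (a blurred pyramid level).
#' @param x,y 0-based interior pixel coordinates.
#' @return A list with `magnitude` and `orientation` (degrees).
#' @export
gradient_at <- function(L, x, y) {
  r <- y + 1L; cc <- x + 1L
  if (r < 2 || cc < 2 || r > nrow(L) - 1 || cc > ncol(L) - 1) {
    abort("Gradient requires an interior pixel.",
          class = "scutematch_invalid_input")
  }
  dx <- L[r, cc + 1] - L[r, cc - 1]
  dy <- L[r + 1, cc] - L[r - 1, cc]
  m <- sqrt(dx^2 + dy^2)
  theta <- if (m == 0) 0 else (atan2(dy, dx) * 180 / pi) %% 360
  list(magnitude = m, orientation = theta)
}

#' Assign orientations to a keypoint
#'
#' Builds a 36-bin gradient-orientation histogram over a circular window
#' of radius three times `orientation_sigma_factor * sigma`, each sample
#' weighted by its gradient magnitude and a Gaussian of that sigma. Every
#' histogram peak that is a strict local maximum and reaches
#' `peak_fraction` of the global maximum spawns an oriented keypoint; the
#' peak angle is refined by parabolic interpolation over three bins. A
#' flat patch (all-zero histogram) discards the keypoint.
#'
#' @param kp A one-row keypoint tibble from [refine_candidate()].
#' @param pyr The [build_scale_space()] pyramid.
#' @param cfg A [sift_config()].
#' @return A tibble of 0 or more oriented keypoints (column `orientation`
#'   in degrees added).
#' @export
assign_orientations <- function(kp, pyr, cfg = sift_config()) {
  oct <- pyr$octaves[[kp$octave]]
  L <- oct$images[[kp$gauss_level]]
  sigma_rel <- kp$sigma / 2^(kp$octave - 1)
  hist <- .orientation_hist_cpp(L, as.integer(round(kp$y_oct)) + 1L,
                                as.integer(round(kp$x_oct)) + 1L,
                                sigma_rel, cfg$n_orientation_bins,
                                cfg$orientation_sigma_factor)
  peaks <- histogram_peaks(hist, cfg$peak_fraction)
  if (length(peaks) == 0) {
    return(kp[0, , drop = FALSE])
  }
  out <- kp[rep(1, length(peaks)), , drop = FALSE]
  out$orientation <- peaks
  out
}

# Peak angles (degrees) of a circular orientation histogram: the raw
# histogram is smoothed with a circular [1,4,6,4,1]/16 kernel (twice) to
# stabilize peaks against sampling noise, then strict local maxima
# reaching `frac` of the global max are parabolically refined.
histogram_peaks <- function(hist, frac) {
  n <- length(hist)
  kern <- c(1, 4, 6, 4, 1) / 16
  for (pass in 1:2) {
    sm <- numeric(n)
    for (s in -2:2) {
      sm <- sm + kern[s + 3] * hist[(seq_len(n) - 1 + s) %% n + 1]
    }
    hist <- sm
  }
  mx <- max(hist)
  if (mx <= 0) return(numeric(0))
  binw <- 360 / n
  peaks <- numeric(0)
  for (b in seq_len(n)) {
    hl <- hist[(b - 2) %% n + 1]
    hr <- hist[b %% n + 1]
    h0 <- hist[b]
    if (h0 >= frac * mx && h0 > hl && h0 > hr) {
      den <- hl - 2 * h0 + hr
      off <- if (den == 0) 0 else 0.5 * (hl - hr) / den
      peaks <- c(peaks, ((b - 1 + 0.5 + off) * binw) %% 360)
    }
  }
  peaks
}

#' Compute a keypoint descriptor
#'
#' Samples the `descriptor_window`-pixel square neighbourhood of the
#' keypoint in its own pyramid level, with coordinates rotated by minus
#' the keypoint orientation. Gradient samples are pooled into
#' `descriptor_subblocks^2` spatial cells of `descriptor_bins` relative-
#' orientation bins with trilinear sharing across position and
#' orientation, each weighted by magnitude and a Gaussian of sigma
#' `descriptor_window / 2` over the window. The concatenated vector (128
#' values at defaults) is normalized to unit length, clamped at
#' `descriptor_clamp` per component, and renormalized. Samples falling
#' outside the image contribute zero; a completely flat patch yields the
#' all-zero vector.
#'
#' @param kp A one-row oriented keypoint tibble.
#' @param pyr The [build_scale_space()] pyramid.
#' @param cfg A [sift_config()].
#' @return A numeric vector of length
#'   `descriptor_subblocks^2 * descriptor_bins`.
#' @export
compute_descriptor <- function(kp, pyr, cfg = sift_config()) {
  oct <- pyr$octaves[[kp$octave]]
  L <- oct$images[[kp$gauss_level]]
  .descriptor_cpp(L, kp$y_oct + 1, kp$x_oct + 1, kp$orientation,
                  cfg$descriptor_window, cfg$descriptor_subblocks,
                  cfg$descriptor_bins, cfg$descriptor_clamp)
}

#' Extract SIFT features from a working image
#'
#' Runs the full feature-extraction chain: scale-space construction,
#' difference-of-Gaussians, 26-neighbour extrema detection, sub-pixel
#' refinement with contrast and edge rejection, orientation assignment and
#' descriptor computation. Deterministic for a fixed input and
#' configuration.
#'
#' @param image A preprocessed [gray_image()] at working resolution.
#' @param cfg A [sift_config()].
#' @param image_id,individual_id,group Labels attached to the result.
#' @return A `feature_set`: list with the labels, a `keypoints` tibble
#'   (`x`, `y`, `octave`, `level`, `sigma`, `response`, `orientation`) and
#'   a parallel `descriptors` matrix (one row per keypoint).
#' @export
extract_features <- function(image, cfg = sift_config(),
                             image_id = "image", individual_id = NA_character_,
                             group = NA_character_) {
  pyr <- build_scale_space(image, cfg)
  dog <- build_dog(pyr)
  cands <- detect_extrema(dog)

  kps <- vector("list", nrow(cands))
  if (nrow(cands) > 0) {
    for (idx in seq_len(nrow(cands))) {
      res <- refine_candidate(cands[idx, ], dog, cfg)
      if (!res$accepted) next
      oriented <- assign_orientations(res$keypoint, pyr, cfg)
      if (nrow(oriented) == 0) next
      kps[[idx]] <- oriented
    }
  }
  kps <- dplyr::bind_rows(kps)

  ndesc <- cfg$descriptor_subblocks^2 * cfg$descriptor_bins
  if (is.null(kps) || nrow(kps) == 0) {
    warn(sprintf("No keypoints found in image '%s'.", image_id))
    return(feature_set(image_id, individual_id, group,
                       keypoints = empty_keypoints(),
                       descriptors = matrix(numeric(0), 0, ndesc),
                       cfg = cfg))
  }
  desc <- matrix(0, nrow(kps), ndesc)
  for (idx in seq_len(nrow(kps))) {
    desc[idx, ] <- compute_descriptor(kps[idx, ], pyr, cfg)
  }
  keep <- c("x", "y", "octave", "level", "sigma", "response", "orientation")
  feature_set(image_id, individual_id, group,
              keypoints = kps[, keep], descriptors = desc, cfg = cfg)
}

empty_keypoints <- function() {
  tibble(x = numeric(), y = numeric(), octave = integer(), level = integer(),
         sigma = numeric(), response = numeric(), orientation = numeric())
}

#' Labelled feature set of an image
#'
#' @param image_id,individual_id,group Labels.
#' @param keypoints Keypoint tibble.
#' @param descriptors Descriptor matrix, one row per keypoint.
#' @param cfg The [sift_config()] used.
#' @return A `feature_set` object.
#' @export
feature_set <- function(image_id, individual_id, group, keypoints,
                        descriptors, cfg) {
  if (nrow(keypoints) != nrow(descriptors)) {
    abort("Keypoints and descriptors must have equal length.",
          class = "scutematch_invalid_input")
  }
  structure(
    list(image_id = image_id, individual_id = individual_id, group = group,
         keypoints = keypoints, descriptors = descriptors,
         config = cfg, config_digest = rlang::hash(cfg)),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> '%s' (individual %s, group %s): %d keypoints\n",
              x$image_id, x$individual_id, x$group, nrow(x$keypoints)))
  invisible(x)
}

#' Tidy a feature set into its keypoint table
#'
#' @param x A `feature_set`.
#' @param ... Unused.
#' @return The keypoint tibble with `image_id` and `individual_id`
#'   prepended.
#' @exportS3Method generics::tidy
tidy.feature_set <- function(x, ...) {
  dplyr::bind_cols(tibble(image_id = rep(x$image_id, nrow(x$keypoints)),
                          individual_id = rep(x$individual_id, nrow(x$keypoints))),
                   x$keypoints)
}

#' Plot keypoints over their image
#'
#' @param object A `feature_set`.
#' @param image Optional [gray_image()] backdrop.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.feature_set <- function(object, image = NULL, ...) {
  p <- if (is.null(image)) {
    ggplot2::ggplot() + ggplot2::scale_y_reverse()
  } else {
    autoplot.gray_image(image)
  }
  p + ggplot2::geom_point(
    data = object$keypoints,
    ggplot2::aes(x = .data$x, y = .data$y, size = .data$sigma),
    colour = "red", shape = 1, inherit.aes = FALSE
  ) +
    ggplot2::labs(size = "scale (px)")
}
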