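#' SIFT configuration
#'
#' Parameters of the scale-invariant feature transform as used for
#' tail-scale pattern recognition. Defaults follow the classical published
#' parameterization: 4 octaves of 5 Gaussian scale levels built with base
#' blur sigma 1.6 and multiplier k = sqrt(2); candidate keypoints are
#' rejected below a difference-of-Gaussians contrast of 0.03 or above a
#' principal-curvature ratio of 10; orientations come from a 36-bin
#' histogram with secondary peaks above 80% of the maximum; descriptors
#' summarize a 16 x 16 neighbourhood in 4 x 4 sub-blocks of 8 orientation
#' bins (128 values), clamped at 0.2 and renormalized.
#'
#' @param n_octaves Number of pyramid octaves.
#' @param n_scale_levels Gaussian images per octave.
#' @param base_sigma Blur scale of the first level of each octave (in that
#'   octave's pixels).
#' @param k_factor Scale multiplier between adjacent levels; must be > 1.
#' @param contrast_threshold Minimum interpolated |DoG| response.
#' @param edge_r Principal-curvature ratio bound r; reject when
#'   tr(H)^2/det(H) >= (r+1)^2/r.
#' @param n_orientation_bins Orientation histogram bins over 360 degrees.
#' @param peak_fraction Relative amplitude for secondary orientation peaks.
#' @param orientation_sigma_factor Gaussian window sigma as a multiple of
#'   the keypoint scale.
#' @param descriptor_window Descriptor neighbourhood side length in pixels.
#' @param descriptor_subblocks Sub-blocks per side.
#' @param descriptor_bins Orientation bins per sub-block.
#' @param descriptor_clamp Maximum descriptor component before the final
#'   renormalization.
#' @return A `sift_config` object.
#' @examples
#' cfg <- sift_config()
#' cfg$descriptor_subblocks^2 * cfg$descriptor_bins  # 128
#' @export
sift_config <- function(n_octaves = 4, n_scale_levels = 5, base_sigma = 1.6,
                        k_factor = sqrt(2), contrast_threshold = 0.03,
                        edge_r = 10, n_orientation_bins = 36,
                        peak_fraction = 0.8, orientation_sigma_factor = 1.5,
                        descriptor_window = 16, descriptor_subblocks = 4,
                        descriptor_bins = 8, descriptor_clamp = 0.2) {
  if (contrast_threshold <= 0) {
    abort("`contrast_threshold` must be > 0.", class = "scutematch_invalid_input")
  }
  if (edge_r < 1) abort("`edge_r` must be >= 1.", class = "scutematch_invalid_input")
  if (k_factor <= 1) abort("`k_factor` must be > 1.", class = "scutematch_invalid_input")
  if (n_scale_levels < 4) {
    abort("Need at least 4 scale levels to search DoG extrema.",
          class = "scutematch_invalid_input")
  }
  structure(
    list(n_octaves = as.integer(n_octaves),
         n_scale_levels = as.integer(n_scale_levels),
         base_sigma = base_sigma, k_factor = k_factor,
         contrast_threshold = contrast_threshold, edge_r = edge_r,
         n_orientation_bins = as.integer(n_orientation_bins),
         peak_fraction = peak_fraction,
         orientation_sigma_factor = orientation_sigma_factor,
         descriptor_window = as.integer(descriptor_window),
         descriptor_subblocks = as.integer(descriptor_subblocks),
         descriptor_bins = as.integer(descriptor_bins),
         descriptor_clamp = descriptor_clamp),
    class = "sift_config"
  )
}

#' @export
print.sift_config <- function(x, ...) {
  cat(sprintf(
    "<sift_config> %d octaves x %d levels, sigma %.2f, k %.3f, contrast %.3f, edge r %.1f\n",
    x$n_octaves, x$n_scale_levels, x$base_sigma, x$k_factor,
    x$contrast_threshold, x$edge_r))
  invisible(x)
}
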