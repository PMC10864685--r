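#' Convert a colour image to grayscale
#'
#' Collapses a 3-channel image to luminance using Rec.601 luma weights
#' (0.299 R + 0.587 G + 0.114 B), the convention of consumer JPEG
#' pipelines.
#'
#' @param image A numeric array `height x width x 3` with channel values in
#'   \[0, 1\].
#' @return A [gray_image()] of the same width and height.
#' @examples
#' arr <- array(0.5, dim = c(4, 4, 3))
#' to_grayscale(arr)
#' @export
to_grayscale <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort("`image` must be a height x width x 3 array.",
          class = "scutematch_invalid_input")
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 1) {
    abort("Channel values must lie in [0, 1].",
          class = "scutematch_invalid_input")
  }
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  as_gray(g)
}

#' Elliptical region of interest
#'
#' Describes the (possibly rotated) ellipse enclosing the patterned surface
#' — for beaver tails, the largest ellipse that fits the dorsal tail area.
#' Coordinates are 0-based pixels; `rotation` is degrees counterclockwise
#' about the centre in the x-right / y-down image frame.
#'
#' @param center_x,center_y Ellipse centre in pixels.
#' @param semi_axis_x,semi_axis_y Semi-axes in pixels; both must be > 0.
#' @param rotation Rotation in degrees (default 0).
#' @return An `ellipse_roi` object.
#' @export
ellipse_roi <- function(center_x, center_y, semi_axis_x, semi_axis_y,
                        rotation = 0) {
  if (semi_axis_x <= 0 || semi_axis_y <= 0) {
    abort("Ellipse semi-axes must be positive.",
          class = "scutematch_invalid_input")
  }
  structure(
    list(center_x = center_x, center_y = center_y,
         semi_axis_x = semi_axis_x, semi_axis_y = semi_axis_y,
         rotation = rotation),
    class = "ellipse_roi"
  )
}

#' Crop an elliptical region from an image
#'
#' Returns the axis-aligned bounding box of the ellipse with every pixel
#' outside the ellipse set to 0. Pixel (x, y) belongs to the ellipse when
#' its centre satisfies the ellipse inequality after rotating into the
#' ellipse frame.
#'
#' @param image A [gray_image()].
#' @param roi An [ellipse_roi()]. Must intersect the image bounds.
#' @return A [gray_image()] covering the ellipse bounding box (clipped to
#'   the image).
#' @export
crop_ellipse <- function(image, roi) {
  stopifnot(inherits(roi, "ellipse_roi"))
  if (!is_gray_image(image)) image <- as_gray(image)
  th <- roi$rotation * pi / 180
  a <- roi$semi_axis_x; b <- roi$semi_axis_y
  # bounding box of the rotated ellipse
  ex <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  ey <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  x0 <- max(0, floor(roi$center_x - ex)); x1 <- min(ncol(image) - 1, ceiling(roi$center_x + ex))
  y0 <- max(0, floor(roi$center_y - ey)); y1 <- min(nrow(image) - 1, ceiling(roi$center_y + ey))
  if (x1 < x0 || y1 < y0) {
    abort("Ellipse does not intersect the image.",
          class = "scutematch_invalid_input")
  }
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - roi$center_x)
  dy <- outer(ys - roi$center_y, rep(1, length(xs)))
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  out <- unclass(image)[ys + 1, xs + 1, drop = FALSE]
  out[!inside] <- 0
  as_gray(out)
}

#' Enhancement parameters
#'
#' Deterministic re-expression of the slider adjustments a consumer photo
#' editor applies to make scale-boundary lines visible. Each slider is
#' mapped to a standard operator (see [enhance()]); two presets,
#' `"close"` and `"far"`, encode the recipes used for the two image-
#' acquisition heights.
#'
#' @param sharpen_amount Unsharp-mask amount as a fraction; 1.5 means
#'   "sharpness 150%"; 1.0 is identity.
#' @param exposure_gain Multiplicative gain in \[1, 5\].
#' @param contrast Contrast on a 0–100 scale; linear stretch about 0.5
#'   with slope `1 + contrast/100`.
#' @param gamma Gamma brightness; pixel map `out = in^(1/gamma)`; must be
#'   > 0.
#' @param lightness_offset Additive shift on a -100..100 scale (applied as
#'   `offset/255`).
#' @param backlight_strength Backlight-compensation strength as a fraction
#'   (1.5 = "150%"); realized as CLAHE with clip limit proportional to the
#'   strength; 0 disables.
#' @param intensify,brighten Local-contrast boosts on a 0–100 scale; folded
#'   into the CLAHE clip limit.
#' @return An `enhance_params` object.
#' @export
enhance_params <- function(sharpen_amount = 1, exposure_gain = 1,
                           contrast = 0, gamma = 1, lightness_offset = 0,
                           backlight_strength = 0, intensify = 0,
                           brighten = 0) {
  if (gamma <= 0) abort("`gamma` must be > 0.", class = "scutematch_invalid_input")
  if (exposure_gain < 1) abort("`exposure_gain` must be >= 1.",
                               class = "scutematch_invalid_input")
  for (nm in c("contrast", "intensify", "brighten")) {
    v <- get(nm)
    if (v < 0 || v > 100) abort(sprintf("`%s` must lie in [0, 100].", nm),
                                class = "scutematch_invalid_input")
  }
  if (abs(lightness_offset) > 100) {
    abort("`lightness_offset` must lie in [-100, 100].",
          class = "scutematch_invalid_input")
  }
  structure(
    list(sharpen_amount = sharpen_amount, exposure_gain = exposure_gain,
         contrast = contrast, gamma = gamma,
         lightness_offset = lightness_offset,
         backlight_strength = backlight_strength,
         intensify = intensify, brighten = brighten),
    class = "enhance_params"
  )
}

#' @rdname enhance_params
#' @param preset `"close"`, `"far"` or `"none"`. The close recipe:
#'   sharpness 150%, exposure 5, contrast 100, gamma 2.5, lightness -40,
#'   backlight 150%, intensify and brighten 100. The far recipe differs in
#'   gamma (3.4), lightness (-15) and backlight (200%).
#' @export
enhance_preset <- function(preset = c("close", "far", "none")) {
  preset <- match.arg(preset)
  switch(preset,
    none  = enhance_params(),
    close = enhance_params(sharpen_amount = 1.5, exposure_gain = 5,
                           contrast = 100, gamma = 2.5,
                           lightness_offset = -40, backlight_strength = 1.5,
                           intensify = 100, brighten = 100),
    far   = enhance_params(sharpen_amount = 1.5, exposure_gain = 5,
                           contrast = 100, gamma = 3.4,
                           lightness_offset = -15, backlight_strength = 2.0,
                           intensify = 100, brighten = 100)
  )
}

#' Enhance an image for pattern extraction
#'
#' Applies the fixed enhancement pipeline: backlight compensation (CLAHE)
#' -> exposure gain -> lightness offset -> contrast stretch -> gamma map ->
#' unsharp-mask sharpening (Gaussian sigma 1.0, amount
#' `sharpen_amount - 1`). Intensities are clipped to \[0, 1\] after each
#' stage; identity parameters return the input unchanged.
#'
#' @param image A [gray_image()].
#' @param params An [enhance_params()] or preset name.
#' @return The enhanced [gray_image()].
#' @export
enhance <- function(image, params = enhance_params()) {
  if (is.character(params)) params <- enhance_preset(params)
  stopifnot(inherits(params, "enhance_params"))
  x <- unclass(as_gray(image))

  clahe_load <- params$backlight_strength > 0 ||
    params$intensify > 0 || params$brighten > 0
  if (clahe_load) {
    limit <- 2 * params$backlight_strength +
      (params$intensify + params$brighten) / 100
    x <- clahe_backlight(x, limit)
  }
  if (params$exposure_gain != 1) x <- clip01(x * params$exposure_gain)
  if (params$lightness_offset != 0) {
    x <- clip01(x + params$lightness_offset / 255)
  }
  if (params$contrast != 0) {
    slope <- 1 + params$contrast / 100
    x <- clip01(0.5 + slope * (x - 0.5))
  }
  if (params$gamma != 1) x <- x^(1 / params$gamma)
  if (params$sharpen_amount != 1) {
    amount <- params$sharpen_amount - 1
    blur <- .gauss_blur_cpp(x, 1.0)
    x <- clip01(x + amount * (x - blur))
  }
  as_gray(x)
}

# CLAHE stand-in for the editor's backlight/intensify/brighten controls.
# Uses EBImage's contrast-limited adaptive histogram equalization on an
# 8x8 tile grid. EBImage stores images x-major, hence the transposes.
clahe_backlight <- function(x, limit) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort(paste("Backlight compensation requires the EBImage package;",
                "set backlight_strength, intensify and brighten to 0",
                "or install EBImage."),
          class = "scutematch_missing_dependency")
  }
  nx <- max(2L, min(8L, ncol(x) %/% 8L))
  ny <- max(2L, min(8L, nrow(x) %/% 8L))
  y <- EBImage::clahe(t(x), nx = nx, ny = ny, limit = limit,
                      keep.range = TRUE)
  t(as.matrix(y))
}

#' Resize to the working resolution
#'
#' Bilinear (corner-aligned) resize to exact target dimensions. The aspect
#' ratio is deliberately not preserved: the reference workflow maps
#' 1330 x 889 originals onto a 640 x 480 working frame.
#'
#' @param image A [gray_image()].
#' @param target_width,target_height Target dimensions in pixels (>= 3).
#' @return A [gray_image()] of exactly the target size.
#' @export
resize_working <- function(image, target_width = 640, target_height = 480) {
  if (target_width < 3 || target_height < 3) {
    abort("Target dimensions must be at least 3 pixels.",
          class = "scutematch_invalid_input")
  }
  x <- unclass(as_gray(image))
  if (nrow(x) == target_height && ncol(x) == target_width) return(as_gray(x))
  as_gray(.resize_bilinear_cpp(x, as.integer(target_height),
                               as.integer(target_width)))
}
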