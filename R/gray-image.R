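#' Grayscale working images
#'
#' All stages of the identification pipeline consume and produce
#' `gray_image` objects: numeric matrices of intensities in \[0, 1\] with
#' rows indexing the vertical axis (y, increasing downward) and columns the
#' horizontal axis (x). This matches the orientation of image files as read
#' by [read_image()].
#'
#' @param x A numeric matrix of intensities in \[0, 1\].
#' @return A `gray_image` object (a classed numeric matrix).
#' @examples
#' img <- gray_image(matrix(runif(12), 3, 4))
#' image_width(img)   # 4
#' image_height(img)  # 3
#' @export
gray_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix.", class = "scutematch_invalid_input")
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 1) {
    abort("Intensities must lie in [0, 1] with no missing values.",
          class = "scutematch_invalid_input")
  }
  structure(x, class = c("gray_image", class(matrix())))
}

#' @rdname gray_image
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

#' @rdname gray_image
#' @export
image_width <- function(x) ncol(x)

#' @rdname gray_image
#' @export
image_height <- function(x) nrow(x)

# clip to [0, 1] preserving dim (pmin/pmax with a scalar first arg drops it)
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# restore class after matrix ops that strip attributes
as_gray <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  structure(as.matrix(x), class = c("gray_image", class(matrix())))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, intensity [%.3f, %.3f]\n",
              ncol(x), nrow(x), min(x), max(x)))
  invisible(x)
}

#' Convert a gray image to a tidy pixel table
#'
#' @param x A [gray_image()].
#' @param ... Unused.
#' @return A tibble with columns `x`, `y` (0-based pixel coordinates) and
#'   `intensity`.
#' @exportS3Method generics::tidy
tidy.gray_image <- function(x, ...) {
  tibble(
    x = rep(seq_len(ncol(x)) - 1L, each = nrow(x)),
    y = rep(seq_len(nrow(x)) - 1L, times = ncol(x)),
    intensity = as.vector(unclass(x))
  )
}

#' Plot a gray image
#'
#' @param object A [gray_image()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gray_image <- function(object, ...) {
  df <- tidy.gray_image(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "intensity") +
    ggplot2::theme_minimal()
}
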