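#' Preprocess an image for feature extraction
#'
#' Grayscale conversion (if needed), optional elliptical crop, optional
#' enhancement preset, and resizing to the working resolution.
#'
#' @param image A [gray_image()], colour array, or file path.
#' @param roi Optional [ellipse_roi()].
#' @param params An [enhance_params()] or preset name (`"none"` skips
#'   enhancement).
#' @param target_width,target_height Working resolution.
#' @return A [gray_image()] at working resolution.
#' @export
prep_image <- function(image, roi = NULL, params = "none",
                       target_width = 640, target_height = 480) {
  if (is.character(image)) image <- read_image(image)
  if (is.array(image) && length(dim(image)) == 3) image <- to_grayscale(image)
  if (!is_gray_image(image)) image <- as_gray(image)
  if (!is.null(roi)) image <- crop_ellipse(image, roi)
  if (is.character(params)) params <- enhance_preset(params)
  image <- enhance(image, params)
  resize_working(image, target_width, target_height)
}

#' Extract features for a whole image collection
#'
#' @param images Named list of [gray_image()]s (names are image ids), or a
#'   manifest tibble with `image_path` and `image_id` columns.
#' @param manifest Tibble with `image_id`, `individual_id`, `group` rows
#'   matching `images`.
#' @param cfg A [sift_config()].
#' @param preprocess If `TRUE`, run [prep_image()] (preset `preset`) on
#'   each image first.
#' @param preset Enhancement preset for preprocessing.
#' @param target_width,target_height Working resolution for preprocessing.
#' @param progress Print one line per image.
#' @return A named list of `feature_set` objects.
#' @export
extract_all <- function(images, manifest, cfg = sift_config(),
                        preprocess = TRUE, preset = "none",
                        target_width = 640, target_height = 480,
                        progress = FALSE) {
  ids <- manifest$image_id
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    id <- ids[i]
    img <- if (is.list(images) && !is.null(images[[id]])) {
      images[[id]]
    } else {
      read_image(manifest$image_path[i])
    }
    if (preprocess) {
      img <- prep_image(img, params = preset,
                        target_width = target_width,
                        target_height = target_height)
    }
    out[[id]] <- extract_features(img, cfg, image_id = id,
                                  individual_id = manifest$individual_id[i],
                                  group = manifest$group[i])
    if (progress) {
      message(sprintf("[%d/%d] %s: %d keypoints", i, length(ids), id,
                      nrow(out[[id]]$keypoints)))
    }
  }
  out
}

#' Run the full identification pipeline
#'
#' End-to-end orchestration: preprocess, extract features, split into
#' database and test sets, identify every test image within its sample
#' block, and aggregate accuracies. Fully reproducible from the
#' configuration seed.
#'
#' @param manifest A manifest tibble (see [load_manifest()]) or a
#'   `synthetic_dataset` from [make_benchmark()].
#' @param config A [run_config()].
#' @param features Optional precomputed named list of feature sets (skips
#'   extraction).
#' @param progress Print progress lines.
#' @return A list with `report` (an `evaluation_report`), `matrices`
#'   (per-sample confusion matrices), `split`, and `config_digest`.
#' @export
run_pipeline <- function(manifest, config = run_config(), features = NULL,
                         progress = FALSE) {
  images <- NULL
  if (inherits(manifest, "synthetic_dataset")) {
    images <- manifest$images
    manifest <- manifest$manifest
  }
  if (is.null(features)) {
    features <- extract_all(images, manifest, cfg = config$sift,
                            preprocess = TRUE, preset = config$preset,
                            target_width = config$working_width,
                            target_height = config$working_height,
                            progress = progress)
  }
  split <- split_dataset(manifest, db_fraction = config$db_fraction,
                         seed = config$seed)
  # assign individuals to sample blocks within each group
  blocks <- list()
  for (grp in unique(manifest$group)) {
    inds <- sort(unique(manifest$individual_id[manifest$group == grp]))
    per <- config$per_sample_individuals
    n_blocks <- max(1L, ceiling(length(inds) / per))
    for (b in seq_len(n_blocks)) {
      sel <- inds[((b - 1) * per + 1):min(b * per, length(inds))]
      blocks[[length(blocks) + 1]] <-
        list(individuals = sel, sample_id = sprintf("%s_s%d", grp, b),
             group = grp)
    }
  }
  matrices <- lapply(blocks, function(bl) {
    if (progress) message(sprintf("evaluating block %s", bl$sample_id))
    evaluate_sample(bl, split, features, config$match)
  })
  report <- aggregate_report(matrices)
  list(report = report, matrices = matrices, split = split,
       config_digest = config_digest(config))
}
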