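#' Read an image file
#'
#' Reads PNG (via the png package), TIFF (via the tiff package) or other
#' formats supported by EBImage when installed. 8-bit files arrive scaled
#' to \[0, 1\]; colour images are converted with [to_grayscale()].
#'
#' @param path File path.
#' @return A [gray_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Image file not found: %s", path),
          class = "scutematch_invalid_input")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("Reading TIFF requires the tiff package.",
            class = "scutematch_missing_dependency")
    }
    tiff::readTIFF(path)
  } else if (requireNamespace("EBImage", quietly = TRUE)) {
    img <- EBImage::readImage(path)
    a <- as.array(img)
    if (length(dim(a)) == 3) aperm(a, c(2, 1, 3)) else t(a)
  } else {
    abort(sprintf("Unsupported image format: .%s", ext),
          class = "scutematch_invalid_input")
  }
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] >= 3) {
      to_grayscale(arr[, , 1:3, drop = FALSE])
    } else {
      as_gray(arr[, , 1])
    }
  } else {
    as_gray(arr)
  }
}

#' Write a gray image as 8-bit PNG
#'
#' @param image A [gray_image()].
#' @param path Output path (.png).
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(unclass(as_gray(image)), path)
  invisible(path)
}

#' Load and validate a dataset manifest
#'
#' A manifest is a CSV with columns `image_path`, `individual_id` and
#' `group`; an `image_id` column is derived from the file name when
#' absent. Missing files are reported with their row numbers.
#'
#' @param path Manifest CSV path.
#' @param check_files Verify that every `image_path` exists.
#' @return A tibble of validated records.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("image_path", "individual_id", "group")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    abort(sprintf("Manifest is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "scutematch_schema_error")
  }
  if (nrow(m) == 0) {
    abort("Manifest is empty.", class = "scutematch_invalid_input")
  }
  if (!"image_id" %in% names(m)) {
    m$image_id <- tools::file_path_sans_ext(basename(m$image_path))
  }
  if (check_files) {
    absent <- !file.exists(m$image_path)
    if (any(absent)) {
      abort(sprintf("Manifest rows with missing files: %s",
                    paste(sprintf("row %d (%s)", which(absent),
                                  m$image_path[absent]),
                          collapse = "; ")),
            class = "scutematch_invalid_input")
    }
  }
  as_tibble(m)
}

#' Save or load a feature database
#'
#' The container holds every feature set (labels, keypoint tables,
#' descriptor matrices) plus the SIFT configuration digest. `load` of a
#' `save` reproduces keypoints and descriptors exactly; loading a
#' database whose configuration digest differs from `expect_digest`
#' fails cleanly.
#'
#' @param db A [feature_db()].
#' @param path File path (`.rds` container).
#' @return `save_database` returns the path invisibly; `load_database`
#'   returns the [feature_db()].
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "feature_db"))
  saveRDS(db, path)
  invisible(path)
}

#' @rdname save_database
#' @param expect_digest Optional configuration digest that the database
#'   must match (e.g. `rlang::hash(sift_config())`).
#' @export
load_database <- function(path, expect_digest = NULL) {
  db <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("Cannot read feature database '%s': %s", path,
                  conditionMessage(e)),
          class = "scutematch_invalid_input")
  })
  if (!inherits(db, "feature_db")) {
    abort(sprintf("'%s' does not contain a feature database.", path),
          class = "scutematch_invalid_input")
  }
  if (!is.null(expect_digest) && !identical(db$config_digest, expect_digest)) {
    abort("Feature database was built with a different configuration.",
          class = "scutematch_config_mismatch")
  }
  db
}

#' Export a feature set as plain text
#'
#' Directory-of-files fallback for the database container: a header CSV
#' (labels and config digest), a keypoint CSV, and a descriptor CSV.
#'
#' @param fs A `feature_set`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_feature_set <- function(fs, dir) {
  stopifnot(inherits(fs, "feature_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble(image_id = fs$image_id,
                          individual_id = fs$individual_id,
                          group = fs$group,
                          config_digest = fs$config_digest),
                   file.path(dir, "header.csv"))
  readr::write_csv(fs$keypoints, file.path(dir, "keypoints.csv"))
  readr::write_csv(as_tibble(as.data.frame(fs$descriptors),
                             .name_repair = "minimal"),
                   file.path(dir, "descriptors.csv"))
  invisible(dir)
}

#' Run configuration
#'
#' Bundles every stage's parameters. Round-trips losslessly through YAML
#' via [save_config()] / [load_config()]; its digest stamps all derived
#' artifacts.
#'
#' @param sift A [sift_config()].
#' @param match A [match_config()].
#' @param preset Enhancement preset name (`"close"`, `"far"`, `"none"`).
#' @param working_width,working_height Working resolution.
#' @param db_fraction,seed,samples,per_sample_individuals Evaluation
#'   settings.
#' @return A `run_config` object.
#' @export
run_config <- function(sift = sift_config(), match = match_config(),
                       preset = "none", working_width = 640,
                       working_height = 480, db_fraction = 0.7, seed = 42,
                       samples = 1, per_sample_individuals = 25) {
  structure(list(sift = sift, match = match, preset = preset,
                 working_width = as.integer(working_width),
                 working_height = as.integer(working_height),
                 db_fraction = db_fraction, seed = as.integer(seed),
                 samples = as.integer(samples),
                 per_sample_individuals = as.integer(per_sample_individuals)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- list(sift = unclass(config$sift), match = unclass(config$match),
                preset = config$preset,
                working_width = config$working_width,
                working_height = config$working_height,
                db_fraction = config$db_fraction, seed = config$seed,
                samples = config$samples,
                per_sample_individuals = config$per_sample_individuals)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  p <- yaml::read_yaml(path)
  run_config(sift = do.call(sift_config, p$sift),
             match = do.call(match_config, p$match),
             preset = p$preset, working_width = p$working_width,
             working_height = p$working_height,
             db_fraction = p$db_fraction, seed = p$seed,
             samples = p$samples,
             per_sample_individuals = p$per_sample_individuals)
}

#' Digest of a configuration
#'
#' @param config Any configuration object.
#' @return A short hash string.
#' @export
config_digest <- function(config) rlang::hash(config)
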