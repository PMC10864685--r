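# round half-up to `digits` decimals, as accuracies are reported
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Split a labelled image collection into database and test sets
#'
#' Stratified random split: every individual keeps at least one image in
#' the database, and the database size equals `round(db_fraction * n)`
#' overall. Per-individual quotas `db_fraction * n_i` are met by
#' largest-remainder allocation, so each individual's database count is
#' within one image of its quota. Individuals with a single image go to
#' the database only (with a warning). Deterministic for a fixed seed.
#'
#' @param items A data frame with at least `image_id` and `individual_id`
#'   columns (extra columns such as `group` are carried through).
#' @param db_fraction Fraction of images for the database, in (0, 1).
#' @param seed Integer seed controlling the split.
#' @return A `dataset_split`: list with tibbles `database_items` and
#'   `test_items`, plus `db_fraction` and `seed`.
#' @export
split_dataset <- function(items, db_fraction = 0.7, seed = 1) {
  items <- as_tibble(items)
  if (!all(c("image_id", "individual_id") %in% names(items))) {
    abort("`items` needs columns image_id and individual_id.",
          class = "scutematch_invalid_input")
  }
  if (db_fraction <= 0 || db_fraction >= 1) {
    abort("`db_fraction` must lie in (0, 1).",
          class = "scutematch_invalid_input")
  }
  singles <- items |>
    dplyr::count(.data$individual_id) |>
    dplyr::filter(.data$n == 1)
  if (nrow(singles) > 0) {
    warn(sprintf("%d individual(s) have a single image; database only.",
                 nrow(singles)))
  }
  n_total <- nrow(items)
  n_db_target <- round(db_fraction * n_total)

  withr::with_seed(seed, {
    shuffled <- items[sample.int(n_total), ]
    per_ind <- shuffled |>
      dplyr::group_by(.data$individual_id) |>
      dplyr::mutate(.ord = dplyr::row_number(), .n = dplyr::n()) |>
      dplyr::ungroup()
    quotas <- per_ind |>
      dplyr::distinct(.data$individual_id, .data$.n) |>
      dplyr::mutate(quota = db_fraction * .data$.n,
                    base = pmax(1L, pmin(.data$.n, as.integer(floor(.data$quota)))),
                    frac = .data$quota - floor(.data$quota))
    remainder <- n_db_target - sum(quotas$base)
    quotas$extra <- 0L
    if (remainder > 0) {
      # +1 to the largest fractional parts; seeded order breaks ties
      order_idx <- order(-quotas$frac, sample.int(nrow(quotas)))
      room <- quotas$base < quotas$.n
      pick <- order_idx[room[order_idx]][seq_len(min(remainder, sum(room)))]
      quotas$extra[pick] <- 1L
    } else if (remainder < 0) {
      order_idx <- order(quotas$frac, sample.int(nrow(quotas)))
      room <- quotas$base > 1L
      pick <- order_idx[room[order_idx]][seq_len(min(-remainder, sum(room)))]
      quotas$extra[pick] <- -1L
    }
    quotas$n_db <- quotas$base + quotas$extra
    per_ind <- dplyr::left_join(per_ind,
                                quotas[, c("individual_id", "n_db")],
                                by = "individual_id")
  })
  db <- per_ind |> dplyr::filter(.data$.ord <= .data$n_db)
  test <- per_ind |> dplyr::filter(.data$.ord > .data$n_db)
  drop_cols <- c(".ord", ".n", "n_db")
  db <- db[, setdiff(names(db), drop_cols)]
  test <- test[, setdiff(names(test), drop_cols)]
  if (nrow(test) == 0) {
    abort("Split leaves no test images; lower db_fraction.",
          class = "scutematch_invalid_input")
  }
  structure(list(database_items = db, test_items = test,
                 db_fraction = db_fraction, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d database / %d test images (fraction %.2f, seed %d)\n",
              nrow(x$database_items), nrow(x$test_items), x$db_fraction,
              x$seed))
  invisible(x)
}

#' Confusion matrix of individual predictions
#'
#' Columns index the actual individual, rows the predicted one; entry
#' (i, j) counts test images of individual j predicted as individual i.
#' Unidentified queries (no prediction) are counted in an extra
#' `"(none)"` row when present.
#'
#' @param actual,predicted Character vectors of individual labels,
#'   parallel over test images; `NA` in `predicted` means no prediction.
#' @param labels Ordered individual labels (default: sorted union).
#' @return A `confusion_matrix` object wrapping the count matrix.
#' @export
confusion_matrix <- function(actual, predicted, labels = NULL) {
  if (length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must have equal length.",
          class = "scutematch_invalid_input")
  }
  if (is.null(labels)) {
    labels <- sort(unique(c(actual, predicted[!is.na(predicted)])))
  }
  row_labels <- labels
  if (anyNA(predicted)) row_labels <- c(labels, "(none)")
  counts <- matrix(0L, nrow = length(row_labels), ncol = length(labels),
                   dimnames = list(predicted = row_labels, actual = labels))
  pred <- ifelse(is.na(predicted), "(none)", predicted)
  for (i in seq_along(actual)) {
    counts[pred[i], actual[i]] <- counts[pred[i], actual[i]] + 1L
  }
  structure(list(labels = labels, counts = counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d individuals, %d test images\n",
              length(x$labels), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Tidy a confusion matrix into long format
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A tibble with `actual`, `predicted`, `n`.
#' @exportS3Method generics::tidy
tidy.confusion_matrix <- function(x, ...) {
  tibble(actual = rep(colnames(x$counts), each = nrow(x$counts)),
         predicted = rep(rownames(x$counts), times = ncol(x$counts)),
         n = as.integer(x$counts))
}

#' Plot a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot tile plot (actual on x, predicted on y).
#' @exportS3Method ggplot2::autoplot
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$predicted,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$n > 0, .data$n, "")),
                       colour = "white", size = 3) +
    ggplot2::scale_fill_gradient(low = "grey20", high = "firebrick") +
    ggplot2::labs(x = "actual individual", y = "predicted individual",
                  fill = "images") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Evaluate identification over a sample block
#'
#' Restricts both the database and the queries to the block's individuals
#' (the reference workflow evaluates four blocks of 25 animals each),
#' identifies every test image, and tabulates actual vs predicted
#' individuals.
#'
#' @param block Character vector of individual labels in the block, or a
#'   `sample_block` list with fields `individuals`, `sample_id`, `group`.
#' @param split A [split_dataset()] result.
#' @param features A named list of `feature_set` objects (names =
#'   image ids) covering all images in the split.
#' @param match_cfg A [match_config()].
#' @return A `confusion_matrix` with attributes `sample_id`, `group` and
#'   `predictions` (a tibble: image_id, actual, predicted, best_image_id,
#'   best_score, tie_broken).
#' @export
evaluate_sample <- function(block, split, features,
                            match_cfg = match_config()) {
  if (is.list(block)) {
    individuals <- block$individuals
    sample_id <- block$sample_id %||% NA_character_
    group <- block$group %||% NA_character_
  } else {
    individuals <- block
    sample_id <- NA_character_
    group <- NA_character_
  }
  if (length(individuals) == 0) {
    abort("Empty sample block.", class = "scutematch_invalid_input")
  }
  db_items <- split$database_items |>
    dplyr::filter(.data$individual_id %in% individuals)
  test_items <- split$test_items |>
    dplyr::filter(.data$individual_id %in% individuals)
  if (nrow(db_items) == 0 || nrow(test_items) == 0) {
    abort("Block has no database or no test images.",
          class = "scutematch_invalid_input")
  }
  db <- feature_db(features[db_items$image_id])
  preds <- purrr::map_dfr(test_items$image_id, function(id) {
    res <- identify(features[[id]], db, match_cfg)
    glance.identification(res)
  })
  preds <- dplyr::left_join(
    preds,
    test_items[, c("image_id", "individual_id")],
    by = c(query_image_id = "image_id")
  ) |>
    dplyr::rename(actual = "individual_id")
  cm <- confusion_matrix(preds$actual, preds$predicted_individual,
                         labels = sort(individuals))
  attr(cm, "sample_id") <- sample_id
  attr(cm, "group") <- group
  attr(cm, "predictions") <- preds
  cm
}

#' Identification accuracy from a confusion matrix
#'
#' Accuracy is the number of correct predictions divided by the total
#' number of predictions; per-individual accuracy divides each diagonal
#' entry by its column (actual) sum, and the mean is taken over
#' individuals with at least one test image. Percentages are displayed
#' rounded half-up to one decimal.
#'
#' @param cm A [confusion_matrix()], or the number of correct predictions
#'   (with `n_total` supplied).
#' @param n_total Total predictions when `cm` is a count.
#' @return An `accuracy_report`: `n_correct`, `n_total`,
#'   `accuracy_percent` (rounded for display), `accuracy_exact`
#'   (unrounded), `per_individual_percent` (named vector),
#'   `mean_per_individual_percent`.
#' @examples
#' accuracy(472, 493)$accuracy_percent  # 95.7
#' @export
accuracy <- function(cm, n_total = NULL) {
  if (is.numeric(cm)) {
    n_correct <- cm
    if (is.null(n_total) || n_total <= 0) {
      abort("`n_total` must be a positive count.",
            class = "scutematch_invalid_input")
    }
    per_ind <- NULL
  } else {
    stopifnot(inherits(cm, "confusion_matrix"))
    counts <- cm$counts
    diag_idx <- cbind(match(cm$labels, rownames(counts)),
                      match(cm$labels, colnames(counts)))
    diag_vals <- counts[diag_idx]
    n_correct <- sum(diag_vals)
    n_total <- sum(counts)
    if (n_total == 0) {
      abort("Confusion matrix has no predictions.",
            class = "scutematch_invalid_input")
    }
    col_tot <- colSums(counts)
    with_tests <- col_tot > 0
    per_ind <- rep(NA_real_, length(cm$labels))
    names(per_ind) <- cm$labels
    per_ind[with_tests] <- 100 * diag_vals[with_tests] / col_tot[with_tests]
  }
  exact <- 100 * n_correct / n_total
  structure(
    list(n_correct = n_correct, n_total = n_total,
         accuracy_percent = round_half_up(exact, 1),
         accuracy_exact = exact,
         per_individual_percent = if (is.null(per_ind)) NULL else
           round_half_up(per_ind, 1),
         mean_per_individual_percent = if (is.null(per_ind)) NA_real_ else
           round_half_up(mean(per_ind, na.rm = TRUE), 1)),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %d/%d correct = %.1f%%",
              x$n_correct, x$n_total, x$accuracy_percent))
  if (!is.na(x$mean_per_individual_percent)) {
    cat(sprintf(" (mean per-individual %.1f%%)",
                x$mean_per_individual_percent))
  }
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.accuracy_report <- function(x, ...) {
  tibble(n_correct = x$n_correct, n_total = x$n_total,
         accuracy_percent = x$accuracy_percent,
         accuracy_exact = x$accuracy_exact,
         mean_per_individual_percent = x$mean_per_individual_percent)
}

#' @exportS3Method generics::tidy
tidy.accuracy_report <- function(x, ...) {
  if (is.null(x$per_individual_percent)) {
    return(tibble(individual_id = character(), accuracy_percent = numeric()))
  }
  tibble(individual_id = names(x$per_individual_percent),
         accuracy_percent = unname(x$per_individual_percent))
}

#' Aggregate per-sample confusion matrices into an overall report
#'
#' Pools correct/total counts across sample blocks and reports the overall
#' accuracy together with per-sample and (when sample matrices carry a
#' `group` attribute) per-group accuracies.
#'
#' @param matrices A list of `confusion_matrix` objects from
#'   [evaluate_sample()].
#' @return An `evaluation_report`: `overall` ([accuracy()] report),
#'   `per_sample` tibble (sample_id, group, n_correct, n_total,
#'   accuracy_percent) and `per_group` tibble.
#' @export
aggregate_report <- function(matrices) {
  if (length(matrices) == 0) {
    abort("Need at least one confusion matrix.",
          class = "scutematch_invalid_input")
  }
  per_sample <- purrr::map_dfr(seq_along(matrices), function(i) {
    cm <- matrices[[i]]
    a <- accuracy(cm)
    tibble(sample_id = attr(cm, "sample_id") %||% as.character(i),
           group = attr(cm, "group") %||% NA_character_,
           n_correct = a$n_correct, n_total = a$n_total,
           accuracy_percent = a$accuracy_percent)
  })
  per_group <- per_sample |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_correct = sum(.data$n_correct),
                     n_total = sum(.data$n_total), .groups = "drop") |>
    dplyr::mutate(accuracy_percent =
                    round_half_up(100 * .data$n_correct / .data$n_total, 1))
  overall <- accuracy(sum(per_sample$n_correct), sum(per_sample$n_total))
  structure(list(overall = overall, per_sample = per_sample,
                 per_group = per_group),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n overall: ")
  print(x$overall)
  cat(" per group:\n")
  print(as.data.frame(x$per_group), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.evaluation_report <- function(x, ...) x$per_sample

#' @exportS3Method generics::glance
glance.evaluation_report <- function(x, ...) glance.accuracy_report(x$overall)

`%||%` <- function(a, b) if (is.null(a)) b else a
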