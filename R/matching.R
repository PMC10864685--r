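#' Matching configuration
#'
#' Parameters for descriptor matching and identification: an exact
#' k-nearest-neighbour search (k = 2) in Euclidean descriptor space,
#' followed by the distance ratio test with threshold 0.75 — a candidate
#' match is kept only when its nearest-neighbour distance is strictly less
#' than 0.75 times the second-nearest distance.
#'
#' @param knn_k Neighbours retrieved per query descriptor; must be >= 2
#'   for the ratio test.
#' @param ratio_threshold Ratio-test threshold in (0, 1).
#' @param min_match_count Minimum best-image match count for a prediction;
#'   below it [identify()] predicts none.
#' @param cross_check If `TRUE`, additionally require each match to be
#'   mutual (off by default: matching is one-directional).
#' @return A `match_config` object.
#' @export
match_config <- function(knn_k = 2, ratio_threshold = 0.75,
                         min_match_count = 0, cross_check = FALSE) {
  if (knn_k < 2) abort("`knn_k` must be >= 2 for the ratio test.",
                       class = "scutematch_invalid_input")
  if (ratio_threshold <= 0 || ratio_threshold >= 1) {
    abort("`ratio_threshold` must lie in (0, 1).",
          class = "scutematch_invalid_input")
  }
  structure(list(knn_k = as.integer(knn_k),
                 ratio_threshold = ratio_threshold,
                 min_match_count = as.integer(min_match_count),
                 cross_check = isTRUE(cross_check)),
            class = "match_config")
}

#' Exact k-nearest-neighbour descriptor search
#'
#' For every query descriptor, the k smallest Euclidean distances among
#' the target descriptors, sorted ascending. The search is exact (a full
#' distance scan), not approximate.
#'
#' @param query,target Descriptor matrices (rows are descriptors).
#' @param k Number of neighbours.
#' @return A tibble with one row per (query, rank): `query` (row index),
#'   `rank`, `target` (row index, `NA` when unmatched), `distance`, and
#'   `unmatched` (`TRUE` for all ranks when the target set has fewer than
#'   `k` descriptors).
#' @export
knn_search <- function(query, target, k = 2) {
  query <- as.matrix(query); target <- as.matrix(target)
  nq <- nrow(query)
  if (nq == 0) {
    return(tibble(query = integer(), rank = integer(), target = integer(),
                  distance = numeric(), unmatched = logical()))
  }
  if (nrow(target) < k) {
    return(tibble(query = rep(seq_len(nq), each = k),
                  rank = rep(seq_len(k), times = nq),
                  target = NA_integer_, distance = NA_real_,
                  unmatched = TRUE))
  }
  res <- .knn_cpp(query, target, as.integer(k))
  tibble(query = rep(seq_len(nq), each = k),
         rank = rep(seq_len(k), times = nq),
         target = as.integer(t(res$index)),
         distance = as.numeric(t(res$distance)),
         unmatched = FALSE)
}

#' Ratio-test filtering of neighbour candidates
#'
#' Keeps a query's nearest neighbour only when `d1 < threshold * d2`
#' (strict), where d1 and d2 are the first and second nearest distances.
#' Degenerate cases (`d2 = 0`, i.e. duplicate descriptors, or unmatched
#' queries) are rejected.
#'
#' @param neighbours Output of [knn_search()] with k >= 2.
#' @param cfg A [match_config()].
#' @return A tibble of accepted matches: `query`, `target`, `distance`.
#' @export
ratio_filter <- function(neighbours, cfg = match_config()) {
  wide <- neighbours |>
    dplyr::filter(.data$rank <= 2) |>
    tidyr::pivot_wider(id_cols = "query", names_from = "rank",
                       values_from = c("target", "distance"))
  ok <- !is.na(wide$distance_1) & !is.na(wide$distance_2) &
    wide$distance_2 > 0 &
    wide$distance_1 < cfg$ratio_threshold * wide$distance_2
  tibble(query = wide$query[ok], target = wide$target_1[ok],
         distance = wide$distance_1[ok])
}

#' Match two feature sets
#'
#' One-directional matching of `a`'s descriptors against `b`'s: a 2-NN
#' search followed by the ratio test. When the two feature sets carry the
#' same `image_id`, the zero-distance self-neighbour is excluded before
#' the ratio test so that self-comparison does not degenerate. With
#' `cross_check = TRUE` in the configuration, matches must also be mutual.
#'
#' @param a Query `feature_set`.
#' @param b Target `feature_set`.
#' @param cfg A [match_config()].
#' @return A `match_result`: list with the two image ids, `n_matches`, and
#'   a `pairs` tibble (`query`, `target`, `distance`).
#' @export
match_images <- function(a, b, cfg = match_config()) {
  stopifnot(inherits(a, "feature_set"), inherits(b, "feature_set"))
  if (!identical(a$config_digest, b$config_digest)) {
    warn("Feature sets come from different SIFT configurations.")
  }
  empty <- tibble(query = integer(), target = integer(), distance = numeric())
  if (nrow(a$descriptors) == 0 || nrow(b$descriptors) == 0) {
    return(match_result(a$image_id, b$image_id, empty))
  }
  self <- identical(a$image_id, b$image_id) &&
    nrow(a$descriptors) == nrow(b$descriptors)
  k <- cfg$knn_k + if (self) 1L else 0L
  nn <- knn_search(a$descriptors, b$descriptors, k = k)
  if (all(nn$unmatched)) return(match_result(a$image_id, b$image_id, empty))
  if (self) {
    # drop each query's own descriptor, then re-rank
    nn <- nn |>
      dplyr::filter(.data$target != .data$query) |>
      dplyr::group_by(.data$query) |>
      dplyr::slice_head(n = cfg$knn_k) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  pairs <- ratio_filter(nn, cfg)
  if (cfg$cross_check && nrow(pairs) > 0) {
    back <- knn_search(b$descriptors, a$descriptors, k = cfg$knn_k)
    back_pairs <- ratio_filter(back, cfg)
    keep <- paste(pairs$query, pairs$target) %in%
      paste(back_pairs$target, back_pairs$query)
    pairs <- pairs[keep, ]
  }
  match_result(a$image_id, b$image_id, pairs)
}

match_result <- function(query_id, target_id, pairs) {
  structure(list(query_image_id = query_id, target_image_id = target_id,
                 n_matches = nrow(pairs), pairs = pairs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s vs %s: %d matches\n",
              x$query_image_id, x$target_image_id, x$n_matches))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.match_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(query_image_id = rep(x$query_image_id, nrow(x$pairs)),
           target_image_id = rep(x$target_image_id, nrow(x$pairs))),
    x$pairs
  )
}

#' Labelled feature database
#'
#' The "marked population" against which query images are identified: a
#' collection of feature sets with known individual identities, all
#' extracted under one SIFT configuration.
#'
#' @param entries A list of `feature_set` objects, each with a non-missing
#'   `individual_id`.
#' @return A `feature_db` object.
#' @export
feature_db <- function(entries) {
  if (length(entries) == 0) {
    abort("A feature database needs at least one entry.",
          class = "scutematch_invalid_input")
  }
  ids <- vapply(entries, function(e) e$individual_id, character(1))
  if (anyNA(ids) || any(!nzchar(ids))) {
    abort("Every database entry needs a non-empty individual_id.",
          class = "scutematch_invalid_input")
  }
  digests <- unique(vapply(entries, function(e) e$config_digest, character(1)))
  if (length(digests) > 1) {
    abort("Database entries mix SIFT configurations.",
          class = "scutematch_config_mismatch")
  }
  structure(list(entries = entries, config_digest = digests),
            class = "feature_db")
}

#' @export
print.feature_db <- function(x, ...) {
  ids <- vapply(x$entries, function(e) e$individual_id, character(1))
  cat(sprintf("<feature_db> %d images of %d individuals\n",
              length(x$entries), length(unique(ids))))
  invisible(x)
}

#' Identify a query image against the database
#'
#' Matches the query feature set against every database image and
#' predicts the individual of the image with the largest ratio-test match
#' count. Ties are broken by (1) the smallest sum of match distances, then
#' (2) the lexicographically smallest image id; `tie_broken` records
#' whether a tie occurred. When the best score is below
#' `min_match_count`, no individual is predicted. A query that is itself a
#' database image keeps its zero-distance matches (it trivially matches
#' itself on every keypoint); the self-neighbour exclusion of
#' [match_images()] applies only to direct image-pair comparison.
#'
#' @param query A `feature_set`.
#' @param db A [feature_db()].
#' @param cfg A [match_config()].
#' @return An `identification` object: `query_image_id`,
#'   `predicted_individual` (`NA` for none), `best_image_id`,
#'   `best_score`, `tie_broken`, and a `scores` tibble with per-database-
#'   image `image_id`, `individual_id`, `n_matches`, `sum_distance`.
#' @export
identify <- function(query, db, cfg = match_config()) {
  stopifnot(inherits(query, "feature_set"))
  if (!inherits(db, "feature_db")) {
    abort("`db` must be a feature_db.", class = "scutematch_invalid_input")
  }
  ids <- vapply(db$entries, function(e) e$image_id, character(1))
  ind_ids <- vapply(db$entries, function(e) e$individual_id, character(1))
  lens <- vapply(db$entries, function(e) nrow(e$descriptors), integer(1))
  if (nrow(query$descriptors) == 0 || sum(lens) == 0) {
    scores <- tibble(image_id = ids, individual_id = ind_ids,
                     n_matches = 0L, sum_distance = 0)
  } else if (!cfg$cross_check) {
    # batched scoring: one distance pass over the concatenated database,
    # identical in result to per-entry match_images
    target <- do.call(rbind, lapply(db$entries, function(e) e$descriptors))
    starts <- as.integer(cumsum(c(0L, head(lens, -1))))
    res <- .match_counts_cpp(query$descriptors, target, starts, lens,
                             cfg$ratio_threshold)
    scores <- tibble(image_id = ids, individual_id = ind_ids,
                     n_matches = as.integer(res$n_matches),
                     sum_distance = res$sum_distance)
  } else {
    # cross-check mode goes through full pairwise matching
    scores <- purrr::map_dfr(db$entries, function(entry) {
      m <- match_images(query, entry, cfg)
      tibble(image_id = entry$image_id, individual_id = entry$individual_id,
             n_matches = m$n_matches,
             sum_distance = sum(m$pairs$distance))
    })
  }
  best_n <- max(scores$n_matches)
  top <- scores[scores$n_matches == best_n, ]
  tie <- nrow(top) > 1
  if (tie) {
    top <- top[order(top$sum_distance, top$image_id), ]
  }
  best <- top[1, ]
  predicted <- if (best_n < cfg$min_match_count) NA_character_ else
    best$individual_id
  structure(
    list(query_image_id = query$image_id,
         predicted_individual = predicted,
         best_image_id = best$image_id,
         best_score = best_n,
         tie_broken = tie,
         scores = scores),
    class = "identification"
  )
}

#' @export
print.identification <- function(x, ...) {
  cat(sprintf("<identification> %s -> %s (best image %s, %d matches%s)\n",
              x$query_image_id,
              ifelse(is.na(x$predicted_individual), "<none>",
                     x$predicted_individual),
              x$best_image_id, x$best_score,
              if (x$tie_broken) ", tie broken" else ""))
  invisible(x)
}

#' Tidy an identification into its per-image score table
#'
#' @param x An `identification`.
#' @param ... Unused.
#' @return The scores tibble with the query id prepended.
#' @exportS3Method generics::tidy
tidy.identification <- function(x, ...) {
  dplyr::bind_cols(
    tibble(query_image_id = rep(x$query_image_id, nrow(x$scores))),
    x$scores
  )
}

#' One-line summary of an identification
#'
#' @param x An `identification`.
#' @param ... Unused.
#' @return A one-row tibble: query id, prediction, best image, score, tie
#'   flag.
#' @exportS3Method generics::glance
glance.identification <- function(x, ...) {
  tibble(query_image_id = x$query_image_id,
         predicted_individual = x$predicted_individual,
         best_image_id = x$best_image_id,
         best_score = x$best_score,
         tie_broken = x$tie_broken)
}
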