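fake_items <- function(n_ind, per_ind, group = "close") {
  tibble::tibble(
    image_id = sprintf("i%03d_v%d", rep(seq_len(n_ind), each = per_ind),
                       rep(seq_len(per_ind), times = n_ind)),
    individual_id = sprintf("i%03d", rep(seq_len(n_ind), each = per_ind)),
    group = group
  )
}

test_that("stratified split reproduces the 70/30 reference arithmetic", {
  items <- fake_items(100, 8)   # 800 images of 100 individuals
  sp <- split_dataset(items, db_fraction = 0.7, seed = 1)
  expect_equal(nrow(sp$database_items), 560)
  expect_equal(nrow(sp$test_items), 240)

  # disjoint and covering
  expect_length(intersect(sp$database_items$image_id, sp$test_items$image_id), 0)
  expect_setequal(c(sp$database_items$image_id, sp$test_items$image_id),
                  items$image_id)

  # every individual keeps at least one database image; per-individual
  # counts stay within one image of the 5.6 quota
  per_db <- table(sp$database_items$individual_id)
  expect_length(per_db, 100)
  expect_true(all(per_db %in% c(5, 6)))
})

test_that("splitting is seed-deterministic and validates inputs", {
  items <- fake_items(10, 4)
  a <- split_dataset(items, 0.7, seed = 7)
  b <- split_dataset(items, 0.7, seed = 7)
  expect_identical(a$database_items, b$database_items)
  c <- split_dataset(items, 0.7, seed = 8)
  expect_false(identical(a$database_items$image_id, c$database_items$image_id))

  expect_error(split_dataset(items, 1.2, 1), class = "scutematch_invalid_input")
  # a fraction that empties the test side errors out
  expect_error(split_dataset(fake_items(8, 2), 0.99, 1),
               class = "scutematch_invalid_input")

  single <- rbind(fake_items(3, 3),
                  tibble::tibble(image_id = "solo_v1",
                                 individual_id = "solo", group = "far"))
  expect_warning(sp <- split_dataset(single, 0.7, 1), "single image")
  expect_true("solo_v1" %in% sp$database_items$image_id)
})

test_that("accuracy arithmetic matches the reference report values", {
  expect_equal(accuracy(472, 493)$accuracy_percent, 95.7)
  expect_equal(accuracy(238, 243)$accuracy_percent, 97.9)
  expect_equal(accuracy(234, 250)$accuracy_percent, 93.6)
  expect_equal(accuracy(59, 60)$accuracy_percent, 98.3)
})

test_that("confusion-matrix accuracy covers diagonal and per-individual", {
  cm <- confusion_matrix(c("a", "a", "b", "b", "b"),
                         c("a", "b", "b", "b", "b"))
  rep <- accuracy(cm)
  expect_equal(rep$n_correct, 4)
  expect_equal(rep$n_total, 5)
  expect_equal(rep$accuracy_percent, 80.0)
  expect_equal(unname(rep$per_individual_percent["a"]), 50.0)
  expect_equal(unname(rep$per_individual_percent["b"]), 100.0)
  expect_equal(rep$mean_per_individual_percent, 75.0)

  all_diag <- confusion_matrix(rep(letters[1:4], 2), rep(letters[1:4], 2))
  expect_equal(accuracy(all_diag)$accuracy_percent, 100.0)

  # permutation invariance to label order
  cm2 <- confusion_matrix(c("b", "b", "b", "a", "a"),
                          c("b", "b", "b", "a", "b"))
  expect_equal(accuracy(cm2)$accuracy_percent, 80.0)
  expect_equal(accuracy(cm2)$mean_per_individual_percent, 75.0)
})

test_that("the reference 25-individual confusion table gives 98.0 mean", {
  # 24 individuals fully correct; individual 1 has one of two images
  # predicted as individual 17
  diag_counts <- c(1, 1, 2, 3, 2, 3, 3, 2, 3, 3, 3, 2, 2, 3, 2, 2, 2, 3,
                   2, 3, 2, 3, 3, 2, 2)
  labels <- sprintf("%02d", 1:25)
  actual <- c(rep(labels, times = diag_counts), labels[1])
  predicted <- c(rep(labels, times = diag_counts), labels[17])
  cm <- confusion_matrix(actual, predicted, labels = labels)
  rep <- accuracy(cm)
  expect_equal(rep$mean_per_individual_percent, 98.0)
  expect_equal(sum(cm$counts), 60)
  expect_equal(cm$counts[labels[17], labels[1]], 1)
})

test_that("unidentified queries are tracked in a (none) row", {
  cm <- confusion_matrix(c("a", "b"), c("a", NA))
  expect_true("(none)" %in% rownames(cm$counts))
  expect_equal(sum(cm$counts), 2)
  expect_equal(accuracy(cm)$n_correct, 1)
})

test_that("aggregation pools counts across samples and groups", {
  cm1 <- confusion_matrix(rep("a", 10), c(rep("a", 9), "b"))
  attr(cm1, "sample_id") <- "close_s1"; attr(cm1, "group") <- "close"
  cm2 <- confusion_matrix(rep("a", 8), c(rep("a", 7), "b"))
  attr(cm2, "sample_id") <- "far_s1"; attr(cm2, "group") <- "far"
  rep <- aggregate_report(list(cm1, cm2))
  expect_equal(rep$overall$n_correct, 16)
  expect_equal(rep$overall$n_total, 18)
  expect_equal(rep$overall$accuracy_percent, 88.9)
  expect_equal(nrow(rep$per_sample), 2)
  expect_equal(sort(rep$per_group$accuracy_percent), c(87.5, 90.0))

  solo <- aggregate_report(list(cm1))
  expect_equal(solo$overall$accuracy_percent,
               accuracy(cm1)$accuracy_percent)
})

test_that("pooling the reference per-group counts gives the overall accuracy", {
  # per-group correct/total counts pooled: (238 + 234) / (243 + 250)
  close <- accuracy(238, 243)
  far <- accuracy(234, 250)
  pooled <- accuracy(close$n_correct + far$n_correct,
                     close$n_total + far$n_total)
  expect_equal(pooled$n_total, 493)
  expect_equal(pooled$accuracy_percent, 95.7)
})
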