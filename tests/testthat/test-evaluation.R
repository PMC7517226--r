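test_that("per-class metrics reproduce direct confusion arithmetic", {
  # depressed: TP=11, FP=9, FN=3, TN=24 on a 47-speaker roster
  true <- c(rep(1L, 14), rep(0L, 33))
  pred <- c(rep(1L, 11), rep(0L, 3), rep(1L, 9), rep(0L, 24))
  m <- per_class_metrics(true, pred)
  expect_equal(round(m$depressed$precision, 2), 0.55)
  expect_equal(round(m$depressed$recall, 2), 0.79)
  expect_equal(round(m$depressed$f1, 2), 0.65)
  expect_equal(round(m$accuracy, 2), 0.74)
  # harmonic-mean consistency is exact, not rounded
  expect_identical(m$depressed$f1,
                   f1_from_pr(m$depressed$precision, m$depressed$recall))

  perfect <- per_class_metrics(c(0, 1, 1), c(0, 1, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$depressed$f1, 1)
  expect_equal(perfect$nondepressed$f1, 1)

  expect_warning(m0 <- per_class_metrics(c(1, 0), c(0, 0)),
                 "never predicted")
  expect_equal(m0$depressed$precision, 0)
  expect_equal(m0$depressed$f1, 0)
  expect_error(per_class_metrics(c(1, 0), c(1)), "same length")
})

test_that("swapping the positive class swaps metric pairs, not accuracy", {
  set.seed(12)
  true <- sample(c(0L, 1L), 40, replace = TRUE)
  pred <- sample(c(0L, 1L), 40, replace = TRUE)
  m <- per_class_metrics(true, pred)
  sw <- per_class_metrics(1L - true, 1L - pred)
  expect_equal(m$accuracy, sw$accuracy)
  expect_equal(m$depressed, sw$nondepressed)
  expect_equal(m$nondepressed, sw$depressed)
})

test_that("F1 is the harmonic mean of precision and recall", {
  expect_equal(round(f1_from_pr(0.55, 0.79), 2), 0.65)
  expect_equal(round(f1_from_pr(0.27, 0.89), 2), 0.41)
  expect_equal(f1_from_pr(1, 1), 1)
  expect_equal(f1_from_pr(0, 0), 0)
})

test_that("relative improvement arithmetic", {
  expect_equal(round(relative_improvement(0.65, 0.41), 1), 58.5)
  expect_equal(round(relative_improvement(0.65, 0.59), 1), 10.2)
  expect_equal(relative_improvement(0.4, 0.4), 0)
  expect_error(relative_improvement(0.5, 0), "undefined")
})

test_that("k-fold splits are speaker-disjoint, stratified and seeded", {
  roster <- data.frame(speaker_id = sprintf("s%02d", 1:10),
                       label = rep(c(0L, 1L), each = 5))
  f <- speaker_kfold_split(roster, n_folds = 5, seed = 2)
  expect_identical(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))               # five folds of two
  expect_length(f, 10L)                         # each speaker exactly once
  # stratification: one speaker of each class per fold
  for (k in 1:5) {
    expect_identical(sum(roster$label[f == k]), 1L)
  }
  expect_identical(f, speaker_kfold_split(roster, n_folds = 5, seed = 2))
  expect_false(identical(f, speaker_kfold_split(roster, 5, seed = 3)))
  expect_error(speaker_kfold_split(roster, n_folds = 11), "more folds")
})

test_that("fold sizes stay within one speaker per class when uneven", {
  roster <- data.frame(speaker_id = sprintf("s%02d", 1:13),
                       label = c(rep(0L, 8), rep(1L, 5)))
  f <- speaker_kfold_split(roster, n_folds = 3, seed = 4)
  for (cl in 0:1) {
    per_fold <- table(factor(f[roster$label == cl], levels = 1:3))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("cross-validation concatenates fold predictions over the test set", {
  train_meta <- data.frame(
    speaker_id = rep(sprintf("tr%d", 1:6), each = 4),
    crop_index = rep(1:4, 6),
    label = rep(c(0L, 1L), each = 12), stringsAsFactors = FALSE)
  test_meta <- data.frame(
    speaker_id = rep(sprintf("te%d", 1:4), each = 3),
    crop_index = rep(1:3, 4),
    label = rep(c(0L, 1L), each = 6), stringsAsFactors = FALSE)
  roster <- data.frame(speaker_id = sprintf("tr%d", 1:6),
                       label = rep(c(0L, 1L), each = 3),
                       split = "train", stringsAsFactors = FALSE)
  ft_train <- fake_features(12, 10, train_meta, seed = 31)
  ft_test <- fake_features(12, 10, test_meta, seed = 32)
  cnn <- cnn_config(N = 2, pool_k = 3, pool_s = 2, n4 = 4, epochs = 2,
                    batch = 8)
  res <- suppressWarnings(
    crossval_evaluate(ft_train, ft_test, roster, cnn,
                      ensemble_config(M = 1, base_seed = 1),
                      n_folds = 2, seed = 6))
  # each of the 4 test speakers predicted once per fold
  expect_identical(nrow(res$predictions), 8L)
  expect_true(all(table(res$predictions$speaker_id) == 2))
  expect_s3_class(res$metrics, "class_metrics")
  expect_identical(sort(unique(res$folds)), 1:2)
  # per-fold averaging variant returns averaged f1 values
  res2 <- suppressWarnings(
    crossval_evaluate(ft_train, ft_test, roster, cnn,
                      ensemble_config(M = 1, base_seed = 1),
                      n_folds = 2, seed = 6, pool_folds = FALSE))
  expect_true(is.numeric(res2$metrics$f1_depressed))
  expect_length(res2$metrics$per_fold, 2L)
})
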