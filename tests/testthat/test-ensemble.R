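test_that("ensemble config validates machine seeds", {
  ens <- ensemble_config(M = 4, base_seed = 5)
  expect_length(ens$seeds, 4L)
  expect_false(anyDuplicated(ens$seeds) > 0)
  expect_error(ensemble_config(M = 2, seeds = c(1L, 1L)), "distinct")
  expect_error(ensemble_config(M = 3, seeds = c(1L, 2L)), "M seeds")
})

test_that("probability-averaging fusion equals its worked arithmetic", {
  tbl <- data.frame(machine_id = rep(1:2, each = 2),
                    speaker_id = "s", crop_index = rep(1:2, 2),
                    prob = c(0.2, 0.8, 0.6, 0.8))
  out <- fuse_method1(tbl)
  expect_equal(out$mean_prob, 0.6)  # sample means (0.4, 0.8) -> 0.6
  expect_identical(out$label, 1L)
})

test_that("probability averaging equals grand-mean thresholding", {
  for (i in 1:25) {
    tbl <- random_pred_table(M = sample(2:5, 1), n_speakers = 4,
                             L = sample(2:6, 1), seed = 1000 + i)
    out <- fuse_method1(tbl)
    grand <- tapply(tbl$prob, tbl$speaker_id, mean)
    expect_equal(out$mean_prob, as.numeric(grand[out$speaker_id]))
    expect_identical(out$label,
                     as.integer(as.numeric(grand[out$speaker_id]) >= 0.5))
  }
})

test_that("pooled-mode fusion counts all machine-sample votes", {
  tbl <- data.frame(machine_id = rep(1:2, each = 3),
                    speaker_id = "s", crop_index = rep(1:3, 2),
                    prob = c(0.9, 0.1, 0.2, 0.8, 0.7, 0.6))
  expect_identical(fuse_method2(tbl)$label, 1L)  # labels {1,0,0,1,1,1}
  # 2-2 tie falls to the seeded coin
  tie <- data.frame(machine_id = rep(1:2, each = 2), speaker_id = "s",
                    crop_index = rep(1:2, 2), prob = c(0.9, 0.1, 0.2, 0.8))
  expect_identical(fuse_method2(tie, tie_seed = 3),
                   fuse_method2(tie, tie_seed = 3))
  expect_true(fuse_method2(tie, tie_seed = 3)$label %in% c(0L, 1L))
})

test_that("speaker-mode fusion takes the mode of machine decisions", {
  tbl <- data.frame(
    machine_id = rep(1:3, each = 3), speaker_id = "s",
    crop_index = rep(1:3, 3),
    # machine decisions: 0, 0, 1
    prob = c(0.1, 0.2, 0.9, 0.3, 0.6, 0.2, 0.9, 0.8, 0.7))
  expect_identical(fuse_method3(tbl)$label, 0L)
})

test_that("with one machine each method reduces to its single-machine rule", {
  for (i in 1:10) {
    tbl <- random_pred_table(M = 1, n_speakers = 5, L = 4, seed = 2000 + i)
    single_mean <- aggregate_speakers(tbl, "mean_prob")
    single_mode <- aggregate_speakers(tbl, "mode", tie_seed = 0L)
    m1 <- fuse_method1(tbl)
    expect_identical(m1$label, single_mean$label)
    expect_equal(m1$mean_prob, single_mean$mean_prob)
    expect_identical(fuse_method2(tbl)$label, single_mode$label)
    expect_identical(fuse_method3(tbl)$label, single_mode$label)
  }
})

test_that("fusion is invariant to machine order and total on random tables", {
  for (i in 1:10) {
    tbl <- random_pred_table(M = 4, n_speakers = 4, L = 3, seed = 3000 + i)
    shuf <- tbl[order(-tbl$machine_id, tbl$crop_index), ]
    for (method in 1:3) {
      a <- fuse_predictions(tbl, method, tie_seed = 1)
      b <- fuse_predictions(shuf, method, tie_seed = 1)
      expect_identical(a$label[order(a$speaker_id)],
                       b$label[order(b$speaker_id)])
      expect_true(all(a$label %in% c(0L, 1L)))
      expect_identical(nrow(a), 4L)
    }
  }
})

test_that("ragged machine coverage is rejected", {
  tbl <- random_pred_table(M = 2, n_speakers = 2, L = 3, seed = 1)
  expect_error(fuse_method1(tbl[-2, ]), "ragged")
})

test_that("trained machines differ by seed but share the training data", {
  set.seed(6)
  x <- array(stats::runif(10 * 8 * 12), c(10, 8, 12))
  y <- rep(c(0L, 1L), 6)
  cnn <- cnn_config(N = 3, pool_k = 3, pool_s = 2, n4 = 4, epochs = 2,
                    batch = 6)
  models <- train_ensemble(x, y, cnn, ensemble_config(M = 2, base_seed = 4))
  expect_length(models, 2L)
  expect_false(identical(models[[1]]$W1, models[[2]]$W1))
  # M = 1 ensemble is exactly the single-model pipeline
  ens1 <- ensemble_config(M = 1, seeds = 123L)
  m_ens <- train_ensemble(x, y, cnn, ens1)[[1]]
  cnn1 <- cnn; cnn1$seed <- 123L
  m_single <- train_model(build_model(cnn1, 10, 8), x, y)
  expect_identical(m_ens$W1, m_single$W1)
})

test_that("F1-vs-M curve validates M and degenerates to sd 0 at pool size", {
  tbl <- random_pred_table(M = 3, n_speakers = 6, L = 4, seed = 9)
  truth <- stats::setNames(rep(c(0L, 1L), 3), unique(tbl$speaker_id))
  expect_error(f1_vs_M_curve(tbl, truth, M_grid = 4), "pool size")
  curve <- suppressWarnings(
    f1_vs_M_curve(tbl, truth, M_grid = 3, n_draws = 10, seed = 1))
  expect_equal(curve$sd_f1, c(0, 0))  # single possible subset
})
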