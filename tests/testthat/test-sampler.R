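test_that("available crop count is integer division of duration", {
  expect_identical(count_available_crops(356, 4), 89L)
  expect_identical(count_available_crops(3.9, 4), 0L)
  expect_identical(count_available_crops(547.29, 4), 136L)
  expect_identical(count_available_crops(c(8, 4, 0), 4), c(2L, 1L, 0L))
})

test_that("sampling-plan optimizer maximizes total balanced samples", {
  expect_identical(optimize_sampling_plan(list(A = c(10, 8, 6),
                                               B = c(9, 7, 3))),
                   list(c = 7L, k = 2L, total = 28L))
  expect_identical(optimize_sampling_plan(list(A = 5, B = 5)),
                   list(c = 5L, k = 1L, total = 10L))
  # engineered roster: 31 speakers/class with 89 crops beats using everyone
  counts <- list(dep = c(rep(89L, 31), rep(10L, 11)),
                 non = c(rep(89L, 31), rep(10L, 69)))
  expect_identical(optimize_sampling_plan(counts),
                   list(c = 89L, k = 31L, total = 5518L))
  expect_error(optimize_sampling_plan(list(A = integer(0), B = 5)),
               "infeasible")
})

test_that("optimizer matches brute-force search on random count tables", {
  brute_best <- function(counts) {
    max(vapply(seq_len(max(unlist(counts))), function(cc) {
      k <- min(vapply(counts, function(x) sum(x >= cc), integer(1)))
      2L * k * cc
    }, integer(1)))
  }
  set.seed(404)
  for (rep in 1:30) {
    counts <- list(a = sample.int(150, sample.int(50, 1), replace = TRUE),
                   b = sample.int(150, sample.int(50, 1), replace = TRUE))
    expect_identical(optimize_sampling_plan(counts)$total,
                     brute_best(counts))
  }
})

test_that("materialized plans satisfy every constraint", {
  roster <- data.frame(
    speaker_id = sprintf("x%d", 1:10),
    label = rep(c(0L, 1L), each = 5),
    split = "train", stringsAsFactors = FALSE)
  durations <- stats::setNames(c(40, 36, 22, 9, 50, 41, 18, 33, 60, 12),
                               roster$speaker_id)
  plan <- materialize_plan(roster, durations, S = 4, seed = 3)
  man <- plan$manifest
  # equal crops per speaker, equal speakers per class, exact balance
  expect_true(all(table(man$speaker_id) == plan$c))
  expect_identical(length(plan$selected[["0"]]), plan$k)
  expect_identical(length(plan$selected[["1"]]), plan$k)
  expect_identical(sum(man$label == 0), sum(man$label == 1))
  expect_identical(nrow(man), plan$total)
  # offsets: aligned, distinct, inside the recording
  for (id in unique(man$speaker_id)) {
    off <- man$offset_s[man$speaker_id == id]
    expect_true(all(off %% 4 == 0))
    expect_false(anyDuplicated(off) > 0)
    expect_true(all(off + 4 <= durations[[id]]))
  }
  # determinism and the mandatory seed
  plan2 <- materialize_plan(roster, durations, S = 4, seed = 3)
  expect_identical(plan, plan2)
  plan3 <- materialize_plan(roster, durations, S = 4, seed = 4)
  expect_false(identical(plan$manifest, plan3$manifest))
  expect_error(materialize_plan(roster, durations, S = 4),
               "seed is required")
})

test_that("selection is seed-free when exactly k speakers are eligible", {
  roster <- data.frame(speaker_id = c("a", "b", "c", "d"),
                       label = c(0L, 0L, 1L, 1L), split = "train",
                       stringsAsFactors = FALSE)
  durations <- stats::setNames(c(20, 20, 20, 20), roster$speaker_id)
  p1 <- materialize_plan(roster, durations, seed = 1)
  p2 <- materialize_plan(roster, durations, seed = 999)
  expect_identical(p1$selected, p2$selected)
  expect_identical(p1$selected[["0"]], c("a", "b"))
})

test_that("test-set cropping caps crops but never drops a speaker", {
  roster <- data.frame(speaker_id = c("long", "short", "one"),
                       label = c(1L, 0L, 1L), split = "test",
                       stringsAsFactors = FALSE)
  durations <- c(long = 800, short = 120, one = 5)
  man <- crop_test_speakers(roster, durations, c_cap = 89)
  expect_identical(sum(man$speaker_id == "long"), 89L)
  expect_identical(sum(man$speaker_id == "short"), 30L)
  expect_identical(sum(man$speaker_id == "one"), 1L)
  man1 <- crop_test_speakers(roster, durations, c_cap = 1)
  expect_true(all(table(man1$speaker_id) == 1))
  expect_warning(
    crop_test_speakers(data.frame(speaker_id = "tiny", label = 0L,
                                  split = "test"),
                       c(tiny = 2), c_cap = 5),
    "shorter than one crop")
})
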