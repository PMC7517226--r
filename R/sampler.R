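# Balanced crop sampling. Long recordings are cut into fixed-length,
# non-overlapping crops ("samples") aligned to multiples of the crop length
# S from the recording start. The training selection solves a simple
# maximization: over candidate crops-per-speaker values c, keep k(c)
# speakers per class (the minimum across classes of speakers having at
# least c crops), and pick the c maximizing the total 2*k*c -- equal crops
# per speaker, equal speakers per class, most samples overall.

#' Number of whole crops available in a recording
#'
#' @param duration Recording duration in seconds (vectorized).
#' @param S Crop length in seconds, default 4.
#' @return Integer vector `floor(duration / S)`.
#' @export
#' @examples
#' count_available_crops(356, 4)   # 89
#' count_available_crops(3.9, 4)   # 0
count_available_crops <- function(duration, S = 4) {
  stopifnot(S > 0, all(duration >= 0))
  as.integer(floor(duration / S))
}

#' Optimize the balanced sampling plan
#'
#' Given the available crop counts of every training speaker in each class,
#' finds the crops-per-speaker value `c` maximizing the total number of
#' training samples `2 * k(c) * c`, where `k(c)` is the number of speakers
#' per class that can supply `c` crops (the minimum over the two classes of
#' the count of speakers with at least `c` available). Only distinct
#' available counts need to be considered as candidates: between two
#' consecutive counts, `k` is constant while `c` is smaller. Ties are
#' broken toward smaller `c`, retaining more speakers and so less
#' per-speaker bias.
#'
#' @param counts A list of two integer vectors of available crop counts,
#'   one per class (names are kept in the output but not interpreted).
#' @return A list with `c` (crops per speaker), `k` (speakers per class)
#'   and `total = 2 * k * c`.
#' @export
#' @examples
#' optimize_sampling_plan(list(A = c(10, 8, 6), B = c(9, 7, 3)))
optimize_sampling_plan <- function(counts) {
  stopifnot(is.list(counts), length(counts) == 2L)
  counts <- lapply(counts, function(x) as.integer(x[x >= 1L]))
  if (any(lengths(counts) == 0L)) {
    stop("infeasible: a class has no speaker with at least one crop")
  }
  cand <- sort(unique(unlist(counts)))
  k_of <- vapply(cand, function(cc) {
    min(vapply(counts, function(x) sum(x >= cc), integer(1L)))
  }, integer(1L))
  total <- 2L * k_of * cand
  feasible <- k_of >= 1L
  if (!any(feasible)) {
    stop("infeasible: classes share no usable crops-per-speaker value")
  }
  best <- which(feasible & total == max(total[feasible]))[1L]  # smallest c
  list(c = cand[best], k = k_of[best], total = total[best])
}

#' Materialize the training sampling plan into a crop manifest
#'
#' Runs [optimize_sampling_plan()] on the training speakers and draws the
#' actual selection: when more than `k` speakers of a class are eligible,
#' `k` are drawn uniformly without replacement; for each selected speaker,
#' `c` of its non-overlapping aligned crop offsets are drawn uniformly
#' without replacement. All randomness is derived from `seed`, which is
#' mandatory and recorded in the plan.
#'
#' @param roster Roster `data.frame` (columns `speaker_id`, `label`,
#'   `split`); only `split == "train"` rows are used.
#' @param durations Named numeric vector of recording durations (seconds),
#'   names are speaker ids.
#' @param S Crop length in seconds, default 4.
#' @param seed Integer seed; refusing to default makes reproducibility
#'   explicit.
#' @return A list of class `sampling_plan` with `c`, `k`, `total`,
#'   `selected` (list of speaker ids per class), `seed`, `S`, and
#'   `manifest`: a `data.frame` with `speaker_id`, `crop_index`,
#'   `offset_s`, `label`, `split`.
#' @export
materialize_plan <- function(roster, durations, S = 4, seed) {
  if (missing(seed)) stop("a seed is required to materialize a plan")
  train <- roster[roster$split == "train", , drop = FALSE]
  if (nrow(train) == 0L) stop("no training speakers in roster")
  if (!all(train$speaker_id %in% names(durations))) {
    stop("durations missing for some training speakers")
  }
  avail <- count_available_crops(durations[train$speaker_id], S)
  names(avail) <- train$speaker_id
  counts <- split(avail, train$label)
  if (length(counts) != 2L) stop("training roster must contain both classes")
  opt <- optimize_sampling_plan(counts)

  selected <- lapply(c("0", "1"), function(cl) {
    ids <- train$speaker_id[train$label == as.integer(cl) &
                              avail[train$speaker_id] >= opt$c]
    if (length(ids) > opt$k) {
      with_seed(derive_seed(seed, "speakers", cl),
                sort(sample(ids, opt$k)))
    } else {
      sort(ids)
    }
  })
  names(selected) <- c("0", "1")

  rows <- lapply(unlist(selected, use.names = FALSE), function(id) {
    n_av <- avail[[id]]
    offs <- with_seed(derive_seed(seed, "offsets", id),
                      sort(sample.int(n_av, opt$c) - 1L) * S)
    data.frame(speaker_id = id, crop_index = seq_len(opt$c),
               offset_s = offs,
               label = train$label[train$speaker_id == id],
               split = "train", stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(c = opt$c, k = opt$k, total = opt$total,
                 selected = selected, seed = as.integer(seed), S = S,
                 manifest = manifest),
            class = "sampling_plan")
}

#' Crop manifest for test speakers
#'
#' Test speakers are never dropped: each contributes
#' `min(c_cap, available)` crops, taken deterministically from the start of
#' the recording (aligned, non-overlapping). The cap mirrors the training
#' crops-per-speaker so no test speaker dominates the sample-level pool.
#'
#' @param roster Roster `data.frame`; only `split == "test"` rows are used.
#' @param durations Named numeric vector of durations (seconds).
#' @param c_cap Maximum crops per speaker, default 89.
#' @param S Crop length in seconds, default 4.
#' @return Manifest `data.frame` (`speaker_id`, `crop_index`, `offset_s`,
#'   `label`, `split`). Speakers with no whole crop are dropped with a
#'   warning (they cannot yield a sample at all).
#' @export
crop_test_speakers <- function(roster, durations, c_cap = 89L, S = 4) {
  stopifnot(c_cap >= 1L)
  test <- roster[roster$split == "test", , drop = FALSE]
  rows <- lapply(seq_len(nrow(test)), function(i) {
    id <- test$speaker_id[i]
    n_av <- count_available_crops(durations[[id]], S)
    if (n_av == 0L) {
      warning("test speaker ", id, " shorter than one crop; dropped")
      return(NULL)
    }
    n_take <- min(c_cap, n_av)
    data.frame(speaker_id = id, crop_index = seq_len(n_take),
               offset_s = (seq_len(n_take) - 1L) * S,
               label = test$label[i], split = "test",
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  if (is.null(manifest)) {
    manifest <- data.frame(speaker_id = character(), crop_index = integer(),
                           offset_s = numeric(), label = integer(),
                           split = character(), stringsAsFactors = FALSE)
  }
  rownames(manifest) <- NULL
  manifest
}
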