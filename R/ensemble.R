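# Ensemble averaging. M machines share one architecture and one training
# set, differing only in their random initialization (and hence batch
# order); their per-sample outputs are fused into speaker decisions by one
# of three orders of averaging:
#   Method 1 -- mean probability over machines per sample, then mean over a
#               speaker's samples, threshold 0.5 (equivalently: the grand
#               mean of all M*L_i probabilities -- the operations commute);
#   Method 2 -- pooled mode over all M*L_i hard sample labels;
#   Method 3 -- per-machine speaker mode, then mode across machines.
# Even-count mode ties fall to a seeded fair coin.

#' Ensemble configuration
#'
#' @param M Number of machines. The canonical operating point is `M = 50`
#'   with Method 1 (probability averaging), the configuration that performs
#'   best in practice.
#' @param method Fusion method, 1, 2 or 3.
#' @param seeds Integer vector of `M` distinct per-machine seeds; defaults
#'   to seeds derived from `base_seed`.
#' @param tie_seed Seed for mode tie-break coins.
#' @param base_seed Used to derive `seeds` when not given.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(M = 50L, method = 1L, seeds = NULL,
                            tie_seed = 0L, base_seed = 1L) {
  M <- as.integer(M)
  stopifnot(M >= 1L, method %in% 1:3)
  if (is.null(seeds)) {
    seeds <- vapply(seq_len(M), function(m)
      derive_seed(base_seed, "machine", m), integer(1L))
  }
  seeds <- as.integer(seeds)
  if (length(seeds) != M) stop("need exactly M seeds")
  if (anyDuplicated(seeds)) stop("machine seeds must be distinct")
  structure(list(M = M, method = as.integer(method), seeds = seeds,
                 tie_seed = as.integer(tie_seed)),
            class = "ensemble_config")
}

#' Train an ensemble of identically configured machines
#'
#' Machine `m` is [train_model()] run with `ens$seeds[m]` as its
#' initialization/shuffling seed; the training data are identical across
#' machines.
#'
#' @param x Sample array `F0 x T0 x L` or `crop_features`.
#' @param y Binary sample labels (defaults to `crop_features` labels).
#' @param cnn A [cnn_config()] (its `seed` field is overridden per
#'   machine).
#' @param ens An [ensemble_config()].
#' @param verbose Print progress per machine.
#' @return List of `M` trained `cnn_model`s.
#' @export
train_ensemble <- function(x, y = NULL, cnn, ens, verbose = FALSE) {
  stopifnot(inherits(cnn, "cnn_config"), inherits(ens, "ensemble_config"))
  if (inherits(x, "crop_features")) {
    if (is.null(y)) y <- x$meta$label
    x <- x$x
  }
  F0 <- dim(x)[1L]; T0 <- dim(x)[2L]
  lapply(seq_len(ens$M), function(m) {
    cfg <- cnn
    cfg$seed <- ens$seeds[m]
    if (verbose) message("training machine ", m, "/", ens$M,
                         " (seed ", cfg$seed, ")")
    train_model(build_model(cfg, F0, T0), x, y)
  })
}

#' Per-machine, per-sample prediction table
#'
#' The substrate of all fusion methods: one row per (machine, speaker,
#' crop) holding the predicted probability.
#'
#' @param models List of trained `cnn_model`s.
#' @param x Sample array or `crop_features`.
#' @param meta Sample metadata (`speaker_id`, `crop_index`), row-aligned
#'   with the third dimension of `x`; defaults to `crop_features` meta.
#' @return `data.frame` with `machine_id`, `speaker_id`, `crop_index`,
#'   `prob`.
#' @export
predict_table <- function(models, x, meta = NULL) {
  if (inherits(x, "crop_features")) {
    if (is.null(meta)) meta <- x$meta
    x <- x$x
  }
  stopifnot(!is.null(meta), nrow(meta) == dim(x)[3L])
  tabs <- lapply(seq_along(models), function(m) {
    data.frame(machine_id = m, speaker_id = meta$speaker_id,
               crop_index = meta$crop_index,
               prob = predict_samples(models[[m]], x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, tabs)
}

# Fusion tables must be rectangular: every machine covers the same
# (speaker, crop) cells.
check_rectangular <- function(tbl) {
  key <- paste(tbl$speaker_id, tbl$crop_index)
  per_machine <- split(key, tbl$machine_id)
  ref <- sort(per_machine[[1L]])
  for (k in per_machine[-1L]) {
    if (!identical(sort(k), ref)) {
      stop("ragged coverage: machines do not cover the same samples")
    }
  }
  invisible(TRUE)
}

#' Fusion Method 1: probability averaging
#'
#' Per-sample mean over machines, then per-speaker mean over samples, then
#' threshold 0.5. Because both steps are plain means over a rectangular
#' table, the result equals thresholding the grand mean of all `M * L_i`
#' probabilities of the speaker.
#'
#' @param tbl Prediction table from [predict_table()].
#' @return `data.frame` with `speaker_id`, `label`, `mean_prob`.
#' @export
fuse_method1 <- function(tbl) {
  check_rectangular(tbl)
  sample_mean <- stats::aggregate(
    prob ~ speaker_id + crop_index, data = tbl, FUN = mean)
  ag <- stats::aggregate(prob ~ speaker_id, data = sample_mean, FUN = mean)
  data.frame(speaker_id = ag$speaker_id,
             label = as.integer(ag$prob >= 0.5),
             mean_prob = ag$prob, stringsAsFactors = FALSE)
}

#' Fusion Method 2: pooled sample-label mode
#'
#' Each speaker gets the most frequent hard label among all `M * L_i` of
#' their (machine, sample) labels; an exact tie falls to the seeded coin.
#'
#' @param tbl Prediction table.
#' @param tie_seed Seed for tie-break coins.
#' @return `data.frame` with `speaker_id`, `label`.
#' @export
fuse_method2 <- function(tbl, tie_seed = 0L) {
  check_rectangular(tbl)
  y <- labels_from_probs(tbl$prob)
  ids <- unique(tbl$speaker_id)
  lab <- vapply(ids, function(id) {
    speaker_label_mode(y[tbl$speaker_id == id], tie_seed, id)
  }, integer(1L))
  data.frame(speaker_id = ids, label = unname(lab), stringsAsFactors = FALSE)
}

#' Fusion Method 3: mode of per-machine speaker modes
#'
#' Each machine first decides every speaker by the mode of its own sample
#' labels; the final label is the mode of the `M` machine decisions. Ties
#' at either level fall to the seeded coin (machine-level coins are folded
#' with the machine id so they are independent).
#'
#' @param tbl Prediction table.
#' @param tie_seed Seed for tie-break coins.
#' @return `data.frame` with `speaker_id`, `label`.
#' @export
fuse_method3 <- function(tbl, tie_seed = 0L) {
  check_rectangular(tbl)
  y <- labels_from_probs(tbl$prob)
  ids <- unique(tbl$speaker_id)
  machines <- unique(tbl$machine_id)
  lab <- vapply(ids, function(id) {
    votes <- vapply(machines, function(m) {
      sel <- tbl$speaker_id == id & tbl$machine_id == m
      # single machine: the coin context reduces to the speaker so that
      # Method 3 is exactly the single-machine mode rule
      ctx <- if (length(machines) == 1L) id else paste0("m", m, ":", id)
      speaker_label_mode(y[sel], tie_seed, ctx)
    }, integer(1L))
    speaker_label_mode(votes, tie_seed, id)
  }, integer(1L))
  data.frame(speaker_id = ids, label = unname(lab), stringsAsFactors = FALSE)
}

#' Fuse a prediction table by the configured method
#'
#' @param tbl Prediction table from [predict_table()].
#' @param method Fusion method 1, 2 or 3.
#' @param tie_seed Seed for mode tie-breaks.
#' @return Speaker-level decision `data.frame`.
#' @export
fuse_predictions <- function(tbl, method = 1L, tie_seed = 0L) {
  switch(as.character(method),
         "1" = fuse_method1(tbl),
         "2" = fuse_method2(tbl, tie_seed),
         "3" = fuse_method3(tbl, tie_seed),
         stop("method must be 1, 2 or 3"))
}

#' F1 as a function of ensemble size
#'
#' Draws random machine subsets from a trained pool and traces the mean and
#' standard deviation of the per-class speaker-level F1 against the number
#' of fused machines: the rising-mean, shrinking-sd signature of ensemble
#' averaging. Subsets are drawn without replacement within a draw and with
#' replacement across draws (near the pool size there are fewer distinct
#' subsets than draws, so duplicates occur; at `M` equal to the pool size
#' the sd is exactly zero).
#'
#' @param tbl Prediction table for the whole machine pool.
#' @param truth Named vector of true speaker labels (names = speaker ids).
#' @param M_grid Ensemble sizes to evaluate.
#' @param n_draws Random subsets per grid point, default 200.
#' @param seed Seed for subset draws.
#' @param method Fusion method, default 1.
#' @param tie_seed Seed for mode tie-breaks.
#' @return `data.frame` with columns `M`, `class` (`"depressed"` /
#'   `"nondepressed"`), `mean_f1`, `sd_f1`.
#' @export
f1_vs_M_curve <- function(tbl, truth, M_grid, n_draws = 200L, seed = 1L,
                          method = 1L, tie_seed = 0L) {
  pool <- unique(tbl$machine_id)
  if (max(M_grid) > length(pool)) {
    stop("M exceeds the machine pool size (", length(pool), ")")
  }
  rows <- list()
  for (M in M_grid) {
    f1_dep <- numeric(n_draws); f1_non <- numeric(n_draws)
    for (d in seq_len(n_draws)) {
      sub <- with_seed(derive_seed(seed, "draw", M, d),
                       sample(pool, M))
      fused <- fuse_predictions(tbl[tbl$machine_id %in% sub, , drop = FALSE],
                                method, tie_seed)
      m <- per_class_metrics(truth[fused$speaker_id], fused$label)
      f1_dep[d] <- m$depressed$f1
      f1_non[d] <- m$nondepressed$f1
    }
    rows[[length(rows) + 1L]] <- data.frame(
      M = M, class = c("depressed", "nondepressed"),
      mean_f1 = c(mean(f1_dep), mean(f1_non)),
      sd_f1 = c(stats::sd(f1_dep), stats::sd(f1_non)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
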