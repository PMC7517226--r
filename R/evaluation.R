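# Speaker-level evaluation: per-class precision/recall/F1 and accuracy
# (each class in turn treated as positive, reported "depressed
# (non-depressed)"), speaker-disjoint stratified k-fold splitting, and the
# relative-improvement arithmetic used to compare systems.

#' Per-class classification metrics
#'
#' For each class treated as positive: `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `f1 = 2PR/(P+R)` (0 when `P + R = 0`); accuracy
#' is shared. When a class is never predicted, its precision is reported as
#' 0 with a warning (a convention needed for total metrics on degenerate
#' runs).
#'
#' @param true,pred Equal-length 0/1 label vectors (1 = depressed).
#' @return An object of class `class_metrics`: list with `accuracy` and,
#'   per class (`depressed`, `nondepressed`), `precision`, `recall`, `f1`.
#' @export
per_class_metrics <- function(true, pred) {
  if (length(true) != length(pred)) {
    stop("true and pred must have the same length")
  }
  if (length(true) == 0L) stop("empty label vectors")
  stopifnot(all(true %in% c(0, 1)), all(pred %in% c(0, 1)))
  one_class <- function(pos) {
    tp <- sum(true == pos & pred == pos)
    fp <- sum(true != pos & pred == pos)
    fn <- sum(true == pos & pred != pos)
    if (tp + fp == 0L) {
      warning("class ", pos, " never predicted; precision reported as 0")
      precision <- 0
    } else {
      precision <- tp / (tp + fp)
    }
    recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    list(precision = precision, recall = recall,
         f1 = f1_from_pr(precision, recall))
  }
  structure(list(accuracy = mean(true == pred),
                 depressed = one_class(1L),
                 nondepressed = one_class(0L)),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  fmt <- function(a, b) sprintf("%.2f (%.2f)", a, b)
  cat("accuracy ", fmt(x$accuracy, x$accuracy),
      "  F1 ", fmt(x$depressed$f1, x$nondepressed$f1),
      "  precision ", fmt(x$depressed$precision, x$nondepressed$precision),
      "  recall ", fmt(x$depressed$recall, x$nondepressed$recall), "\n",
      sep = "")
  invisible(x)
}

#' F1 from precision and recall
#'
#' Harmonic mean `2PR/(P+R)`, defined as 0 when both are zero.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return The F1 score.
#' @export
#' @examples
#' f1_from_pr(0.55, 0.79)  # ~0.65
f1_from_pr <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Relative improvement in percent
#'
#' @param f1_new,f1_ref New and reference scores; `f1_ref` must be
#'   positive.
#' @return `100 * (f1_new - f1_ref) / f1_ref`.
#' @export
#' @examples
#' relative_improvement(0.65, 0.41)  # ~58.5
relative_improvement <- function(f1_new, f1_ref) {
  if (f1_ref <= 0) stop("relative improvement undefined for f1_ref <= 0")
  100 * (f1_new - f1_ref) / f1_ref
}

#' Speaker-disjoint stratified k-fold split
#'
#' Every speaker lands in exactly one fold; folds are class-stratified
#' (class ratio preserved within one speaker) and their sizes differ by at
#' most one per class. Assignment is a seeded shuffle within each class
#' followed by round-robin dealing.
#'
#' @param roster Roster `data.frame` (`speaker_id`, `label`).
#' @param n_folds Number of folds, default 5; at most the number of
#'   speakers.
#' @param seed Shuffle seed.
#' @return Named integer vector: fold index (1..n_folds) per speaker id.
#' @export
speaker_kfold_split <- function(roster, n_folds = 5L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds > nrow(roster)) {
    stop("more folds (", n_folds, ") than speakers (", nrow(roster), ")")
  }
  stopifnot(n_folds >= 2L)
  fold <- integer(nrow(roster))
  names(fold) <- roster$speaker_id
  for (cl in unique(roster$label)) {
    idx <- which(roster$label == cl)
    ord <- with_seed(derive_seed(seed, "fold", cl), sample(idx))
    fold[ord] <- rep_len(seq_len(n_folds), length(ord))
  }
  fold
}

#' Cross-validated ensemble evaluation against a fixed test set
#'
#' The training roster is split into speaker-disjoint stratified folds. For
#' each fold, an ensemble is trained on the samples of the speakers
#' *outside* that fold (the held-in fold plays the role of an unused
#' validation subset: no early stopping is performed) and the fixed test
#' set is predicted and fused. Finally the per-fold speaker-level
#' prediction lists are concatenated -- each test speaker counted once per
#' fold -- and the metrics are computed on the concatenation. Set
#' `pool_folds = FALSE` to average per-fold metrics instead.
#'
#' @param train_features,test_features `crop_features` for the training
#'   samples and the test samples.
#' @param roster Roster covering the training speakers (`speaker_id`,
#'   `label`).
#' @param cnn A [cnn_config()].
#' @param ens An [ensemble_config()]; machine seeds are re-derived per fold.
#' @param n_folds Number of folds, default 5.
#' @param seed Fold-assignment seed.
#' @param pool_folds Concatenate fold predictions before scoring (default)
#'   or average per-fold metric values.
#' @param verbose Print fold progress.
#' @return List with `predictions` (`data.frame`: `fold`, `speaker_id`,
#'   `true`, `pred`), `metrics` (a `class_metrics`; for
#'   `pool_folds = FALSE` a list with averaged `f1` values instead) and
#'   `folds`.
#' @export
crossval_evaluate <- function(train_features, test_features, roster,
                              cnn, ens, n_folds = 5L, seed = 1L,
                              pool_folds = TRUE, verbose = FALSE) {
  stopifnot(inherits(train_features, "crop_features"),
            inherits(test_features, "crop_features"))
  train_roster <- roster[roster$split == "train", , drop = FALSE]
  folds <- speaker_kfold_split(train_roster, n_folds, seed)
  truth <- test_features$meta$label[!duplicated(test_features$meta$speaker_id)]
  names(truth) <- unique(test_features$meta$speaker_id)

  preds <- list()
  fold_metrics <- list()
  for (f in seq_len(n_folds)) {
    keep_ids <- names(folds)[folds != f]
    sel <- train_features$meta$speaker_id %in% keep_ids
    x <- train_features$x[, , sel, drop = FALSE]
    y <- train_features$meta$label[sel]
    if (verbose) message("fold ", f, ": ", sum(sel), " training samples")
    ens_f <- ens
    ens_f$seeds <- vapply(seq_len(ens$M), function(m)
      derive_seed(seed, "fold-machine", f, m), integer(1L))
    models <- train_ensemble(x, y, cnn, ens_f)
    tbl <- predict_table(models, test_features$x, test_features$meta)
    fused <- fuse_predictions(tbl, ens$method, ens$tie_seed)
    preds[[f]] <- data.frame(fold = f, speaker_id = fused$speaker_id,
                             true = unname(truth[fused$speaker_id]),
                             pred = fused$label, stringsAsFactors = FALSE)
    if (!pool_folds) {
      fold_metrics[[f]] <- per_class_metrics(preds[[f]]$true,
                                             preds[[f]]$pred)
    }
  }
  predictions <- do.call(rbind, preds)
  metrics <- if (pool_folds) {
    per_class_metrics(predictions$true, predictions$pred)
  } else {
    list(f1_depressed = mean(vapply(fold_metrics, function(m)
           m$depressed$f1, numeric(1L))),
         f1_nondepressed = mean(vapply(fold_metrics, function(m)
           m$nondepressed$f1, numeric(1L))),
         per_fold = fold_metrics)
  }
  list(predictions = predictions, metrics = metrics, folds = folds)
}
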