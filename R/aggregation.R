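# Sample -> speaker aggregation. Two rules: the mode of the per-sample hard
# labels, or the mean of the per-sample probabilities thresholded at 0.5.
# All threshold comparisons use >= (a probability of exactly 0.5 maps to
# the depressed class); exact mode ties are resolved by a seeded fair coin
# so decisions are random by design yet reproducible.

#' Hard labels from probabilities
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param threshold Decision threshold, default 0.5; comparison is `>=`.
#' @return Integer vector of 0/1 labels (empty input passes through).
#' @export
labels_from_probs <- function(p, threshold = 0.5) {
  stopifnot(all(p >= 0 & p <= 1))
  as.integer(p >= threshold)
}

#' Speaker label as the mode of sample labels
#'
#' @param y Integer vector of 0/1 sample labels, non-empty.
#' @param tie_seed Seed for the fair coin used on an exact tie; required if
#'   a tie can occur.
#' @param speaker_id Context folded into the tie coin so outcomes are
#'   independent across speakers under one `tie_seed`.
#' @return A single 0/1 label.
#' @export
speaker_label_mode <- function(y, tie_seed = NULL, speaker_id = "") {
  if (length(y) == 0L) stop("cannot take the mode of zero samples")
  stopifnot(all(y %in% c(0, 1)))
  n1 <- sum(y == 1)
  n0 <- length(y) - n1
  if (n1 > n0) return(1L)
  if (n0 > n1) return(0L)
  if (is.null(tie_seed)) {
    stop("mode tie: a tie_seed is required for the random decision")
  }
  coin_flip(tie_seed, "mode", speaker_id)
}

#' Speaker label from the mean sample probability
#'
#' @param p Numeric vector of sample probabilities, non-empty.
#' @param threshold Decision threshold on the mean, default 0.5 (`>=`).
#' @return A single 0/1 label.
#' @export
#' @examples
#' speaker_label_mean_prob(c(0.4, 0.4, 0.9))  # mean 0.567 -> 1
speaker_label_mean_prob <- function(p, threshold = 0.5) {
  if (length(p) == 0L) stop("cannot average zero probabilities")
  stopifnot(all(p >= 0 & p <= 1))
  as.integer(mean(p) >= threshold)
}

#' Aggregate a single machine's sample predictions per speaker
#'
#' @param tbl Prediction table `data.frame` with columns `speaker_id` and
#'   `prob` (one machine's per-sample probabilities).
#' @param method `"mean_prob"` ([speaker_label_mean_prob()]) or `"mode"`
#'   ([speaker_label_mode()] over thresholded labels).
#' @param tie_seed Seed for mode tie-breaks.
#' @return `data.frame` with `speaker_id` and `label` (plus `mean_prob`
#'   for the mean-probability rule).
#' @export
aggregate_speakers <- function(tbl, method = c("mean_prob", "mode"),
                               tie_seed = 0L) {
  method <- match.arg(method)
  ids <- unique(tbl$speaker_id)
  if (method == "mean_prob") {
    mp <- vapply(ids, function(id) mean(tbl$prob[tbl$speaker_id == id]),
                 numeric(1L))
    data.frame(speaker_id = ids, label = as.integer(mp >= 0.5),
               mean_prob = unname(mp), stringsAsFactors = FALSE)
  } else {
    lab <- vapply(ids, function(id) {
      speaker_label_mode(labels_from_probs(tbl$prob[tbl$speaker_id == id]),
                         tie_seed, id)
    }, integer(1L))
    data.frame(speaker_id = ids, label = unname(lab),
               stringsAsFactors = FALSE)
  }
}
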