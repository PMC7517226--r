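# Log-spectrogram features. A 4-s crop at 16 kHz becomes a 513 x 125
# matrix: magnitude STFT over 64 ms Hamming windows every 32 ms with 1024
# FFT points, log-compressed, then min-max normalized per spectrogram.
#
# Frame-count convention: T0 = floor(n_samples / hop). For the canonical
# crop this gives 64000 / 512 = 125 exactly, which matches neither plain
# non-centered framing (124) nor fully centered framing (126); we use
# centered frames (window t centered on sample (t-1)*hop, zero-padded at
# the edges) and drop the final boundary frame, reproducing the canonical
# geometry deterministically for any crop length.

#' Compute a log-magnitude spectrogram
#'
#' @param samples Numeric waveform (one crop), at `rate`.
#' @param rate Sampling rate, default 16000 Hz.
#' @param win_ms Analysis window length in ms (Hamming), default 64.
#' @param hop_ms Hop between frames in ms, default 32.
#' @param nfft FFT length, default 1024 (window is zero-padded up to it).
#' @param eps Log floor added to the magnitude before the logarithm,
#'   default `1e-10`: silence maps to `log(eps)` instead of `-Inf`, and the
#'   floor sits far below any voiced magnitude.
#' @param speaker_id,crop_index Optional provenance tags stored as
#'   attributes.
#' @return A `log_spectrogram`: numeric matrix of dimension
#'   `(nfft/2 + 1) x floor(n/hop)` (frequency x time) with attributes
#'   `normalized = FALSE`, `params`, `speaker_id`, `crop_index`.
#' @export
#' @examples
#' sp <- compute_log_spectrogram(sin(2 * pi * 440 * (1:64000) / 16000))
#' dim(sp)  # 513 125
compute_log_spectrogram <- function(samples, rate = 16000L,
                                    win_ms = 64, hop_ms = 32, nfft = 1024L,
                                    eps = 1e-10,
                                    speaker_id = NA_character_,
                                    crop_index = NA_integer_) {
  win_n <- round(win_ms * rate / 1000)
  hop_n <- round(hop_ms * rate / 1000)
  n <- length(samples)
  if (n < win_n) {
    stop("crop shorter than one analysis window (", win_n, " samples)")
  }
  stopifnot(nfft >= win_n)
  t0 <- n %/% hop_n

  # centered framing: frame t covers padded samples starting at (t-1)*hop
  pad_front <- win_n %/% 2L
  need <- (t0 - 1L) * hop_n + win_n
  pad_back <- max(0L, need - (n + pad_front))
  xp <- c(numeric(pad_front), samples, numeric(pad_back))

  idx <- outer(seq_len(win_n), (seq_len(t0) - 1L) * hop_n, "+")
  frames <- matrix(xp[idx], nrow = win_n) * signal::hamming(win_n)
  if (nfft > win_n) {
    frames <- rbind(frames, matrix(0, nfft - win_n, t0))
  }
  mag <- Mod(stats::mvfft(frames))[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  structure(log(mag + eps),
            class = c("log_spectrogram", "matrix", "array"),
            normalized = FALSE,
            params = list(rate = rate, win_ms = win_ms, hop_ms = hop_ms,
                          nfft = nfft, eps = eps),
            speaker_id = speaker_id, crop_index = crop_index)
}

#' Min-max normalize a log-spectrogram to [0, 1]
#'
#' Per-spectrogram normalization `(x - min) / (max - min)`; each crop is
#' standardized independently of every other. A constant input (e.g. pure
#' silence) maps to all zeros. Because the log turns waveform gain into an
#' additive constant, min-max normalization makes the feature invariant to
#' any positive rescaling of the crop.
#'
#' @param spec A `log_spectrogram` (or plain numeric matrix).
#' @return The normalized matrix, `normalized` attribute set to `TRUE`.
#' @export
minmax_normalize <- function(spec) {
  r <- range(spec)
  out <- if (r[2] > r[1]) (spec - r[1]) / (r[2] - r[1])
         else array(0, dim(spec))
  attributes(out) <- attributes(spec)
  attr(out, "normalized") <- TRUE
  out
}

#' Extract normalized log-spectrogram features for a crop manifest
#'
#' Cuts each manifest crop out of its recording, computes the
#' log-spectrogram and min-max normalizes it. Recordings are fetched
#' through `get_audio`, so corpora can live in memory or on disk (see
#' [audio_loader_memory()], [audio_loader_dir()]); each recording is loaded
#' once.
#'
#' @param get_audio Function `speaker_id -> audio_recording`.
#' @param manifest Crop manifest (`speaker_id`, `crop_index`, `offset_s`,
#'   `label`, `split`), as produced by [materialize_plan()] /
#'   [crop_test_speakers()].
#' @param S Crop length in seconds, default 4.
#' @param ... Passed to [compute_log_spectrogram()].
#' @return A list of class `crop_features`: `x` (array `F0 x T0 x L`),
#'   `meta` (the manifest, row-aligned with the third array dimension) and
#'   `params` (STFT parameters).
#' @export
extract_features <- function(get_audio, manifest, S = 4, ...) {
  stopifnot(nrow(manifest) > 0L)
  first <- NULL
  out <- NULL
  params <- NULL
  row <- 0L
  for (id in unique(manifest$speaker_id)) {
    rec <- get_audio(id)
    stopifnot(inherits(rec, "audio_recording"))
    crop_n <- round(S * rec$rate)
    rows <- which(manifest$speaker_id == id)
    for (i in rows) {
      a <- round(manifest$offset_s[i] * rec$rate) + 1L
      b <- a + crop_n - 1L
      if (b > length(rec$samples)) {
        stop("crop beyond recording end for speaker ", id,
             " at offset ", manifest$offset_s[i])
      }
      sp <- minmax_normalize(compute_log_spectrogram(
        rec$samples[a:b], rate = rec$rate,
        speaker_id = id, crop_index = manifest$crop_index[i], ...))
      if (is.null(out)) {
        first <- dim(sp)
        params <- attr(sp, "params")
        out <- array(0, c(first, nrow(manifest)))
      }
      row <- row + 1L
      out[, , row] <- sp
    }
  }
  # meta rows follow extraction order (grouped by speaker)
  meta <- manifest[unlist(lapply(unique(manifest$speaker_id), function(id)
    which(manifest$speaker_id == id))), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(x = out, meta = meta, params = params),
            class = "crop_features")
}

#' Audio loaders
#'
#' `audio_loader_memory()` serves recordings from a named list (as returned
#' by [simulate_corpus()]); `audio_loader_dir()` reads
#' `<dir>/<speaker_id>.wav` on demand via [load_participant_audio()].
#'
#' @param recordings Named list of `audio_recording` objects.
#' @return A function `speaker_id -> audio_recording`.
#' @export
audio_loader_memory <- function(recordings) {
  function(id) {
    rec <- recordings[[id]]
    if (is.null(rec)) stop("no recording for speaker ", id)
    rec
  }
}

#' @rdname audio_loader_memory
#' @param dir Directory containing `<speaker_id>.wav` files.
#' @param annotation Optional segment annotation `data.frame` applied to
#'   every recording.
#' @param ... Passed to [load_participant_audio()].
#' @export
audio_loader_dir <- function(dir, annotation = NULL, ...) {
  function(id) {
    load_participant_audio(file.path(dir, paste0(id, ".wav")), id,
                           annotation = annotation, ...)
  }
}
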