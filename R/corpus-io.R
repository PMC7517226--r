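# Corpus I/O: speaker roster (CSV), participant-segment annotations (CSV),
# and participant audio loading with resampling and optional silence
# trimming. Diarization itself is out of scope: the segment CSV is the
# interface standing in for a diarizer's output, and pre-cleaned audio is
# accepted directly.

PHQ8_THRESHOLD <- 10L

#' Binarize a PHQ-8 score into a depression label
#'
#' The eight-item Patient Health Questionnaire yields an integer severity
#' score in 0--24; scores greater than or equal to 10 are conventionally
#' classed as depressed.
#'
#' @param score Integer vector of PHQ-8 scores in `[0, 24]`.
#' @return Integer vector of labels: 1 (depressed) where `score >= 10`,
#'   else 0.
#' @export
#' @examples
#' binarize_phq8(c(0, 9, 10, 24))
binarize_phq8 <- function(score) {
  if (!is.numeric(score) || any(is.na(score)) ||
      any(score != floor(score))) {
    stop("PHQ-8 scores must be integers")
  }
  if (any(score < 0 | score > 24)) {
    bad <- which(score < 0 | score > 24)[1L]
    stop("PHQ-8 score out of [0, 24] at position ", bad, ": ", score[bad])
  }
  as.integer(score >= PHQ8_THRESHOLD)
}

#' Load a speaker roster from a label CSV
#'
#' The table must have columns `speaker_id` and `phq8`, and may have a
#' `split` column (`train`/`test`); when `split` is absent every speaker is
#' assigned to `train`. The binary `label` column is always recomputed from
#' `phq8` via [binarize_phq8()].
#'
#' @param path Path to a CSV file with header `speaker_id,phq8[,split]`.
#' @param exclude Character vector of speaker ids to drop (e.g. known
#'   low-quality recordings); default none.
#' @return A `data.frame` with columns `speaker_id` (character), `phq8`
#'   (integer), `label` (integer 0/1) and `split` (character).
#' @export
load_roster <- function(path, exclude = character()) {
  if (!file.exists(path)) stop("label table not found: ", path)
  tab <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  for (col in c("speaker_id", "phq8")) {
    if (!col %in% names(tab)) {
      stop("label table is missing required column '", col, "'")
    }
  }
  phq8 <- suppressWarnings(as.integer(tab$phq8))
  if (any(is.na(phq8))) {
    bad <- which(is.na(phq8))[1L]
    stop("row ", bad, ": phq8 value '", tab$phq8[bad],
         "' is not an integer")
  }
  if (any(phq8 < 0 | phq8 > 24)) {
    bad <- which(phq8 < 0 | phq8 > 24)[1L]
    stop("row ", bad, " (speaker ", tab$speaker_id[bad],
         "): phq8 score ", phq8[bad], " outside [0, 24]")
  }
  if (anyDuplicated(tab$speaker_id)) {
    dup <- tab$speaker_id[duplicated(tab$speaker_id)][1L]
    stop("duplicate speaker_id in roster: ", dup)
  }
  split <- if ("split" %in% names(tab)) tab$split else
    rep("train", nrow(tab))
  if (!all(split %in% c("train", "test"))) {
    stop("split values must be 'train' or 'test'")
  }
  roster <- data.frame(
    speaker_id = tab$speaker_id,
    phq8 = phq8,
    label = binarize_phq8(phq8),
    split = split,
    stringsAsFactors = FALSE
  )
  roster[!roster$speaker_id %in% exclude, , drop = FALSE]
}

#' Write a speaker roster to CSV
#'
#' Inverse of [load_roster()]: writes `speaker_id,phq8,split` (the label
#' column is derived, so it is not stored).
#'
#' @param roster Roster `data.frame` as returned by [load_roster()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(roster[, c("speaker_id", "phq8", "split")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load segment annotations
#'
#' Reads a CSV with header `speaker_id,start_s,stop_s,who`, the interface
#' standing in for diarization output: `who` is `participant` or
#' `interviewer`, times are seconds from the start of the recording.
#' Segments are sorted by start time and validated to be non-overlapping
#' within each `(speaker_id, who)` stream.
#'
#' @param path Path to the segment CSV.
#' @return A `data.frame` with columns `speaker_id`, `start_s`, `stop_s`,
#'   `who`, sorted by speaker then start time.
#' @export
load_segments <- function(path) {
  if (!file.exists(path)) stop("segment table not found: ", path)
  seg <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(speaker_id = "character"))
  for (col in c("speaker_id", "start_s", "stop_s", "who")) {
    if (!col %in% names(seg)) {
      stop("segment table is missing required column '", col, "'")
    }
  }
  if (!all(seg$who %in% c("participant", "interviewer"))) {
    stop("segment 'who' must be 'participant' or 'interviewer'")
  }
  if (any(seg$start_s < 0) || any(seg$start_s >= seg$stop_s)) {
    stop("segments must satisfy 0 <= start_s < stop_s")
  }
  seg <- seg[order(seg$speaker_id, seg$who, seg$start_s), , drop = FALSE]
  for (key in split(seq_len(nrow(seg)),
                    paste(seg$speaker_id, seg$who))) {
    if (length(key) > 1L) {
      s <- seg[key, ]
      if (any(s$start_s[-1L] < s$stop_s[-nrow(s)])) {
        stop("overlapping segments for speaker ", s$speaker_id[1L])
      }
    }
  }
  rownames(seg) <- NULL
  seg
}

# Constructor for the canonical in-memory recording object.
audio_recording <- function(speaker_id, samples, rate) {
  structure(
    list(speaker_id = speaker_id, samples = as.numeric(samples),
         rate = as.integer(rate),
         duration = length(samples) / rate),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording %s: %.2f s @ %d Hz>\n",
              x$speaker_id, x$duration, x$rate))
  invisible(x)
}

#' Resample a waveform to a target rate
#'
#' Polyphase resampling (windowed-sinc filter bank via the `signal`
#' package). Any rational rate conversion is accepted.
#'
#' @param samples Numeric waveform.
#' @param from Input rate (Hz).
#' @param to Target rate (Hz), default 16000.
#' @return Numeric waveform at rate `to`.
#' @export
resample_audio <- function(samples, from, to = 16000L) {
  from <- as.integer(from); to <- as.integer(to)
  if (from == to) return(as.numeric(samples))
  g <- gcd_int(from, to)
  as.numeric(signal::resample(samples, to %/% g, from %/% g))
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Energy-based silence trimming
#'
#' Fallback cleanup when no segment annotation is available: the waveform is
#' divided into non-overlapping 25 ms frames, the RMS energy of each frame
#' is computed, frames whose RMS falls below a fraction of the recording's
#' peak frame RMS are dropped, and the survivors are concatenated.
#'
#' @param samples Numeric waveform.
#' @param rate Sampling rate (Hz).
#' @param frame_s Frame length in seconds (default 0.025).
#' @param threshold Fraction of peak frame RMS below which a frame is
#'   dropped (default 0.005, i.e. 0.5%).
#' @return The concatenated voiced portion of the waveform.
#' @export
trim_silence <- function(samples, rate, frame_s = 0.025, threshold = 0.005) {
  flen <- max(1L, round(frame_s * rate))
  n_frames <- length(samples) %/% flen
  if (n_frames == 0L) return(samples)
  head_n <- n_frames * flen
  fr <- matrix(samples[seq_len(head_n)], nrow = flen)
  rms <- sqrt(colMeans(fr^2))
  keep <- rms >= threshold * max(rms)
  kept <- as.numeric(fr[, keep, drop = FALSE])
  c(kept, samples[seq_len(length(samples) - head_n) + head_n])
}

#' Load one participant's audio
#'
#' Reads a WAV file, averages to mono, resamples to the canonical rate, and
#' isolates the participant's speech: if a segment annotation is given, the
#' `participant` segments are cut out and concatenated in time order
#' (replacing diarization); otherwise optional energy-based silence trimming
#' ([trim_silence()]) is applied.
#'
#' @param path Path to the WAV file.
#' @param speaker_id Speaker identifier attached to the returned recording.
#' @param annotation Optional segment `data.frame` (from [load_segments()]);
#'   rows for other speakers are ignored. `NULL` to skip.
#' @param trim `TRUE` to apply energy-based silence trimming when no
#'   annotation is given.
#' @param target_rate Canonical rate, default 16000 Hz.
#' @return An `audio_recording` at `target_rate`.
#' @export
load_participant_audio <- function(path, speaker_id,
                                   annotation = NULL,
                                   trim = FALSE,
                                   target_rate = 16000L) {
  wav <- read_wav(path)
  x <- resample_audio(wav$samples, wav$rate, target_rate)
  if (!is.null(annotation)) {
    seg <- annotation[annotation$speaker_id == speaker_id &
                        annotation$who == "participant", , drop = FALSE]
    if (nrow(seg) == 0L) {
      stop("empty recording: no participant segments for speaker ",
           speaker_id)
    }
    seg <- seg[order(seg$start_s), , drop = FALSE]
    pieces <- lapply(seq_len(nrow(seg)), function(i) {
      a <- max(1L, floor(seg$start_s[i] * target_rate) + 1L)
      b <- min(length(x), floor(seg$stop_s[i] * target_rate))
      if (b < a) numeric(0) else x[a:b]
    })
    x <- unlist(pieces, use.names = FALSE)
  } else if (isTRUE(trim)) {
    x <- trim_silence(x, target_rate)
  }
  if (length(x) == 0L) {
    stop("empty recording for speaker ", speaker_id)
  }
  audio_recording(speaker_id, x, target_rate)
}
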