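# Synthetic interview corpus. Emulates the statistical structure the
# pipeline assumes -- a roster of speakers with heterogeneous recording
# durations, class imbalance derived from a PHQ-8-like score, and a
# class-dependent acoustic signature -- so every downstream stage is
# testable without access-restricted clinical data.
#
# The class signal is placed in slow pitch modulation and high-band (spectral
# tilt) energy, quantities that survive per-spectrogram min-max
# normalization; mean amplitude deliberately carries no information. Voices
# of the depressed class are flatter: modulation depth and high-band energy
# are both scaled by (1 - 0.8 * effect), emulating the monotonous, reduced
# prosody that motivates speech-based screening.

#' Synthetic corpus configuration
#'
#' @param n_per_class Speakers per class (classes are balanced at the
#'   roster level; the natural imbalance of clinical corpora is emulated by
#'   the caller through `n_per_class`-asymmetric rosters if desired).
#' @param duration_mean,duration_sd Mean/sd (seconds) of the truncated
#'   normal law for per-speaker recording duration; truncation at 4 s (one
#'   crop). Defaults mirror a typical cleaned interview corpus
#'   (547.29 +/- 237.58 s).
#' @param effect Class-separation strength in `[0, 1]`: 0 makes the two
#'   classes generatively identical, 1 gives the maximum contrast (the
#'   depressed class keeps 20% of the modulation depth and high-band
#'   energy).
#' @param test_frac Fraction of speakers (per class) assigned to the test
#'   split, default 0.25.
#' @param rate Sampling rate, default 16000 Hz.
#' @param seed Global corpus seed. Per-speaker seeds are derived from it by
#'   a counter-based scheme, so growing the roster leaves earlier speakers'
#'   audio unchanged.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 20L,
                         duration_mean = 547.29,
                         duration_sd = 237.58,
                         effect = 1,
                         test_frac = 0.25,
                         rate = 16000L,
                         seed = 1L) {
  stopifnot(n_per_class >= 1L, duration_mean >= 4,
            duration_sd >= 0, effect >= 0, effect <= 1,
            test_frac >= 0, test_frac < 1)
  structure(
    list(n_per_class = as.integer(n_per_class),
         duration_mean = duration_mean, duration_sd = duration_sd,
         effect = effect, test_frac = test_frac,
         rate = as.integer(rate), seed = as.integer(seed)),
    class = "synth_config"
  )
}

# PHQ-8-like score draw consistent with the label/threshold invariant:
# non-depressed scores live in [0, 9], depressed in [10, 24].
draw_phq8 <- function(label) {
  if (label == 1L) 10L + stats::rbinom(1L, 14L, 0.3)
  else stats::rbinom(1L, 9L, 0.35)
}

# Truncated-normal duration, truncated below at one crop length (4 s).
draw_duration <- function(mean_s, sd_s) {
  if (sd_s == 0) return(mean_s)
  repeat {
    d <- stats::rnorm(1L, mean_s, sd_s)
    if (d >= 4) return(d)
  }
}

#' Generate one speaker's synthetic voice-like recording
#'
#' The waveform is a harmonic complex (fundamental near 120 Hz, 20
#' harmonics with 1/h roll-off) whose pitch carries slow random modulation
#' (a 3-component sinusoidal drift in 0.5--3 Hz), plus high-pass shaped
#' noise above 3 kHz and a low-level broadband floor. For a depressed-class
#' speaker the pitch-modulation depth and the high-band energy are both
#' scaled by `(1 - 0.8 * effect)`; with `effect = 0` the two classes share
#' one generative law. Deterministic given `seed`.
#'
#' @param label Binary class label (0 non-depressed, 1 depressed).
#' @param duration Recording length in seconds, at least 4.
#' @param effect Class-separation strength in `[0, 1]`.
#' @param seed Integer seed; same seed, same waveform, bit for bit.
#' @param speaker_id Identifier attached to the recording.
#' @param rate Sampling rate, default 16000 Hz.
#' @return An `audio_recording`.
#' @export
generate_speaker_audio <- function(label, duration, effect, seed,
                                   speaker_id = "synth", rate = 16000L) {
  stopifnot(label %in% c(0L, 1L), effect >= 0, effect <= 1)
  if (duration < 4) stop("duration must be at least 4 s (one crop)")
  n <- round(duration * rate)
  atten <- 1 - 0.8 * effect * (label == 1L)

  x <- with_seed(seed, {
    f0 <- stats::rnorm(1L, 120, 10)
    mod_f <- stats::runif(3L, 0.5, 3)
    mod_ph <- stats::runif(3L, 0, 2 * pi)
    mod_a <- stats::runif(3L)
    mod_a <- mod_a / sum(mod_a)
    tt <- seq_len(n) / rate
    m <- numeric(n)
    for (j in 1:3) m <- m + mod_a[j] * sin(2 * pi * mod_f[j] * tt + mod_ph[j])

    depth <- 0.25 * atten
    phase <- 2 * pi * cumsum(f0 * (1 + depth * m)) / rate
    voiced <- numeric(n)
    for (h in 1:20) voiced <- voiced + sin(h * phase) / h
    voiced <- voiced * (0.15 / sqrt(mean(voiced^2)))

    hp <- signal::butter(4, 3000 / (rate / 2), type = "high")
    hband <- as.numeric(signal::filter(hp, stats::rnorm(n)))
    hband <- hband * (0.08 * atten / sqrt(mean(hband^2)))

    floor_noise <- stats::rnorm(n, sd = 0.005)
    out <- voiced + hband + floor_noise
    out / max(1, max(abs(out)) / 0.99)
  })
  audio_recording(speaker_id, x, rate)
}

# Roster skeleton: ids, labels, scores, durations, split and per-speaker
# audio seeds, all reproducible from the corpus seed.
synth_roster <- function(config) {
  n <- 2L * config$n_per_class
  labels <- rep(c(0L, 1L), each = config$n_per_class)
  speaker_id <- sprintf("S%03d", seq_len(n))
  phq8 <- integer(n); duration <- numeric(n)
  for (i in seq_len(n)) {
    with_seed(derive_seed(config$seed, "roster", i), {
      phq8[i] <- draw_phq8(labels[i])
      duration[i] <- draw_duration(config$duration_mean, config$duration_sd)
    })
  }
  split <- rep("train", n)
  n_test <- floor(config$test_frac * config$n_per_class)
  if (n_test > 0L) {
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      pick <- with_seed(derive_seed(config$seed, "split", cl),
                        sample(idx, n_test))
      split[pick] <- "test"
    }
  }
  data.frame(speaker_id = speaker_id, phq8 = phq8, label = labels,
             split = split, duration = duration,
             audio_seed = vapply(seq_len(n), function(i)
               derive_seed(config$seed, "speaker", i), integer(1L)),
             stringsAsFactors = FALSE)
}

#' Simulate a corpus in memory
#'
#' Like [generate_corpus()] but returns the recordings as a list instead of
#' writing WAV files; intended for small test corpora where holding all
#' audio in memory is cheap.
#'
#' @param config A [synth_config()].
#' @return A list with `roster` (data.frame including `duration`) and
#'   `recordings` (named list of `audio_recording`).
#' @export
simulate_corpus <- function(config) {
  roster <- synth_roster(config)
  recordings <- lapply(seq_len(nrow(roster)), function(i) {
    generate_speaker_audio(roster$label[i], roster$duration[i],
                           config$effect, roster$audio_seed[i],
                           speaker_id = roster$speaker_id[i],
                           rate = config$rate)
  })
  names(recordings) <- roster$speaker_id
  list(roster = roster, recordings = recordings)
}

#' Generate a synthetic corpus on disk
#'
#' Writes one WAV per speaker (`audio/<speaker_id>.wav`), a label CSV
#' (`labels.csv` with `speaker_id,phq8,split`), a trivial all-participant
#' segment CSV (`segments.csv`), and a JSON manifest echoing the full
#' configuration for provenance. Audio is generated and written one speaker
#' at a time, so arbitrarily long corpora stream without holding all
#' waveforms in memory. Fully reproducible from `config$seed`.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `roster`, and the paths `audio_dir`,
#'   `labels`, `segments`, `manifest`.
#' @export
generate_corpus <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  audio_dir <- file.path(out_dir, "audio")
  ok <- dir.create(audio_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(audio_dir)) stop("cannot create output directory: ", out_dir)

  roster <- synth_roster(config)
  for (i in seq_len(nrow(roster))) {
    rec <- generate_speaker_audio(roster$label[i], roster$duration[i],
                                  config$effect, roster$audio_seed[i],
                                  speaker_id = roster$speaker_id[i],
                                  rate = config$rate)
    write_wav(rec$samples, rec$rate,
              file.path(audio_dir, paste0(roster$speaker_id[i], ".wav")))
  }

  labels_path <- file.path(out_dir, "labels.csv")
  write_roster(roster, labels_path)

  seg <- data.frame(speaker_id = roster$speaker_id, start_s = 0,
                    stop_s = round(roster$duration, 3), who = "participant")
  segments_path <- file.path(out_dir, "segments.csv")
  utils::write.csv(seg, segments_path, row.names = FALSE, quote = FALSE)

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(unclass(config), manifest_path, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(roster = roster, audio_dir = audio_dir,
                 labels = labels_path, segments = segments_path,
                 manifest = manifest_path))
}
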