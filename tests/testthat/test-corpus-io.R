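test_that("PHQ-8 binarization respects the clinical threshold", {
  expect_identical(binarize_phq8(10), 1L)
  expect_identical(binarize_phq8(9), 0L)
  expect_identical(binarize_phq8(0), 0L)
  expect_identical(binarize_phq8(24), 1L)
  expect_error(binarize_phq8(25), "out of")
  expect_error(binarize_phq8(-1), "out of")
  expect_error(binarize_phq8(9.5), "integer")
  # monotone non-decreasing over the whole score range
  labs <- binarize_phq8(0:24)
  expect_true(all(diff(labs) >= 0))
})

test_that("roster loading validates, labels and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("speaker_id,phq8", "303,10", "304,9", "305,0"), path)
  roster <- load_roster(path)
  expect_identical(roster$label, c(1L, 0L, 0L))
  expect_identical(roster$split, rep("train", 3))

  out <- withr::local_tempfile(fileext = ".csv")
  write_roster(roster, out)
  expect_identical(load_roster(out), roster)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("speaker_id,score", "1,5"), bad)
  expect_error(load_roster(bad), "missing required column")
  writeLines(c("speaker_id,phq8", "1,5", "2,25"), bad)
  expect_error(load_roster(bad), "row 2.*outside", perl = TRUE)
  writeLines(c("speaker_id,phq8", "1,5", "1,7"), bad)
  expect_error(load_roster(bad), "duplicate")
})

test_that("roster exclusion list drops named speakers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("speaker_id,phq8,split", "a,12,train", "b,3,test"), path)
  expect_identical(load_roster(path, exclude = "a")$speaker_id, "b")
})

test_that("WAV files round-trip through write/read", {
  x <- 0.8 * sin(2 * pi * 220 * (1:8000) / 16000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 16000, path)
  wav <- read_wav(path)
  expect_identical(wav$rate, 16000L)
  expect_equal(wav$samples, x, tolerance = 1e-4)  # PCM16 quantization
})

test_that("stereo WAV input is averaged to mono", {
  # hand-built stereo PCM16 file: L = 0.5, R = -0.5 throughout
  path <- withr::local_tempfile(fileext = ".wav")
  con <- file(path, "wb")
  n <- 100L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n * 4L, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, 2L), con, size = 2L, endian = "little")
  writeBin(c(16000L, 64000L), con, size = 4L, endian = "little")
  writeBin(c(4L, 16L), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n * 4L, con, size = 4L, endian = "little")
  writeBin(rep(c(16384L, -16384L), n), con, size = 2L, endian = "little")
  close(con)
  wav <- read_wav(path)
  expect_length(wav$samples, n)
  expect_true(all(abs(wav$samples) < 1e-4))
})

test_that("participant segments are concatenated in time order", {
  rec <- generate_speaker_audio(0, 10, 0, seed = 5)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec$samples, rec$rate, path)
  ann <- data.frame(speaker_id = "s1",
                    start_s = c(0, 5), stop_s = c(3, 9),
                    who = "participant")
  out <- load_participant_audio(path, "s1", annotation = ann)
  expect_equal(out$duration, 7, tolerance = 1 / 16000)

  ann2 <- data.frame(speaker_id = "s1", start_s = 0, stop_s = 10,
                     who = "interviewer")
  expect_error(load_participant_audio(path, "s1", annotation = ann2),
               "empty recording")
})

test_that("audio is canonicalized to 16 kHz from any input rate", {
  x <- sin(2 * pi * 440 * (1:44100) / 44100)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 44100, path)
  out <- load_participant_audio(path, "s1")
  expect_identical(out$rate, 16000L)
  expect_equal(out$duration, 1, tolerance = 0.01)
})

test_that("segment table validation catches malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("speaker_id,start_s,stop_s,who",
               "a,0,3,participant", "a,5,9,participant",
               "a,3,5,interviewer"), path)
  seg <- load_segments(path)
  expect_identical(nrow(seg), 3L)
  writeLines(c("speaker_id,start_s,stop_s,who", "a,3,2,participant"), path)
  expect_error(load_segments(path), "start_s < stop_s")
  writeLines(c("speaker_id,start_s,stop_s,who",
               "a,0,5,participant", "a,4,9,participant"), path)
  expect_error(load_segments(path), "overlapping")
})

test_that("silence trimming removes quiet frames and keeps loud ones", {
  rate <- 16000
  loud <- sin(2 * pi * 200 * (1:rate) / rate)
  quiet <- numeric(rate)
  x <- c(loud, quiet, loud)
  trimmed <- trim_silence(x, rate)
  expect_lt(length(trimmed), length(x))
  expect_equal(length(trimmed) / rate, 2, tolerance = 0.1)
})
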