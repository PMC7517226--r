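# Minimal RIFF/WAVE I/O. Reads mono or multichannel PCM16/PCM8/float32 WAV
# (multichannel averaged to mono), writes mono PCM16. Chunk-based parser:
# unknown chunks are skipped, so files with LIST/fact/cue chunks load fine.

#' Read a WAV file
#'
#' Parses a RIFF/WAVE file and returns the waveform as a numeric vector in
#' `[-1, 1]`. Supported encodings: PCM 8-bit unsigned, PCM 16-bit signed and
#' IEEE float 32-bit. Multichannel audio is averaged down to mono.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector, mono) and `rate`
#'   (samples/second).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # total size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format   = readBin(body[1:2], "integer", 1L, 2L, endian = "little"),
        channels = readBin(body[3:4], "integer", 1L, 2L, endian = "little"),
        rate     = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1L, 2L, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      seek(con, size, origin = "current")
    }
    if (size %% 2L == 1L) seek(con, 1L, origin = "current")  # pad byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV (missing fmt/data chunk): ", path)
  }

  x <- switch(
    as.character(fmt$format),
    "1" = {  # integer PCM
      if (fmt$bits == 16L) {
        readBin(data_raw, "integer", length(data_raw) / 2L, size = 2L,
                signed = TRUE, endian = "little") / 32768
      } else if (fmt$bits == 8L) {
        (readBin(data_raw, "integer", length(data_raw), size = 1L,
                 signed = FALSE) - 128) / 128
      } else {
        stop("unsupported PCM bit depth: ", fmt$bits)
      }
    },
    "3" = readBin(data_raw, "double", length(data_raw) / 4L, size = 4L,
                  endian = "little"),
    stop("unsupported WAV format code: ", fmt$format)
  )

  if (fmt$channels > 1L) {
    n <- (length(x) %/% fmt$channels) * fmt$channels
    x <- rowMeans(matrix(x[seq_len(n)], ncol = fmt$channels, byrow = TRUE))
  }
  list(samples = as.numeric(x), rate = fmt$rate)
}

#' Write a mono PCM16 WAV file
#'
#' @param samples Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param rate Sampling rate in samples/second.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0L, rate > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")          # PCM
  writeBin(1L, con, size = 2L, endian = "little")          # mono
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")          # block align
  writeBin(16L, con, size = 2L, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
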