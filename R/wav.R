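# Minimal RIFF/WAVE reader and writer for mono recordings.
# Supports PCM 16-bit (format 1) and IEEE float32 (format 3), the two
# encodings song-recording rigs in this field actually emit.

#' Construct an audio clip
#'
#' The in-memory carrier of raw song audio: a numeric sample vector plus its
#' sample rate.  Samples are unit-free; 16-bit PCM input is rescaled to
#' [-1, 1).
#'
#' @param samples numeric vector of samples.
#' @param sample_rate sampling rate in Hz (> 0).
#' @return an object of class `audio_clip` with elements `samples` and
#'   `sample_rate`.
#' @export
audio_clip <- function(samples, sample_rate) {
  assert_that(is.numeric(samples) && length(samples) >= 1,
              "samples must be a non-empty numeric vector")
  assert_that(is.numeric(sample_rate) && length(sample_rate) == 1 &&
                is.finite(sample_rate) && sample_rate > 0,
              "sample_rate must be a single positive number")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d samples @ %g Hz (%.1f ms)\n",
              length(x$samples), x$sample_rate,
              1000 * length(x$samples) / x$sample_rate))
  invisible(x)
}

duration_ms <- function(clip) 1000 * length(clip$samples) / clip$sample_rate

#' Read a mono WAV file
#'
#' Reads PCM 16-bit or IEEE float32 mono WAV.  Stereo (or any multi-channel)
#' input is rejected: song analyses here are single-channel by construction.
#'
#' @param path path to a `.wav` file.
#' @return an [audio_clip].
#' @export
read_wav <- function(path) {
  assert_that(file.exists(path), sprintf("WAV file not found: %s", path),
              "songeval_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  assert_that(identical(riff, "RIFF"), sprintf("not a RIFF file: %s", path),
              "songeval_io_error")
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  assert_that(identical(wave, "WAVE"), sprintf("not a WAVE file: %s", path),
              "songeval_io_error")

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        format    = readBin(raw_fmt[1:2], "integer", 1, 2, signed = FALSE,
                            endian = "little"),
        channels  = readBin(raw_fmt[3:4], "integer", 1, 2, signed = FALSE,
                            endian = "little"),
        rate      = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits      = readBin(raw_fmt[15:16], "integer", 1, 2, signed = FALSE,
                            endian = "little"))
    } else if (identical(id, "data")) {
      assert_that(!is.null(fmt), "malformed WAV: data chunk before fmt",
                  "songeval_io_error")
      if (fmt$format == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", size / 2, 2, signed = TRUE,
                           endian = "little") / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", size / 4, 4, endian = "little")
      } else {
        stop_songeval(sprintf(
          "unsupported WAV encoding (format %d, %d bits); use PCM16 or float32",
          fmt$format, fmt$bits), "songeval_io_error")
      }
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)  # skip unknown chunk (word-aligned)
    }
    if (!is.null(samples)) break
  }
  assert_that(!is.null(samples), sprintf("no data chunk in %s", path),
              "songeval_io_error")
  assert_that(fmt$channels == 1L,
              sprintf("expected mono WAV, got %d channels: %s",
                      fmt$channels, path))
  audio_clip(samples, fmt$rate)
}

#' Write a mono WAV file (PCM 16-bit)
#'
#' Samples are clipped to [-1, 1] before quantization.
#'
#' @param clip an [audio_clip].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  assert_that(inherits(clip, "audio_clip"), "clip must be an audio_clip")
  x <- pmax(pmin(clip$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  sr <- as.integer(round(clip$sample_rate))
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
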