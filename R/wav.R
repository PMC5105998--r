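#' Read a RIFF/WAVE audio file
#'
#' Minimal WAV reader covering the formats used for stimulus clips:
#' integer PCM (16/24/32 bit) and IEEE float32/float64, mono or multichannel.
#' Samples are returned as amplitudes in `[-1, 1]` (float data as stored).
#'
#' @param path Path to a `.wav` file.
#' @param clip_id Identifier attached to the returned clip; defaults to the
#'   file name without extension.
#' @return An `audio_clip`: list with `samples` (numeric vector, first channel
#'   if multichannel), `rate` (Hz) and `clip_id`.
#' @export
read_wav <- function(path, clip_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("not a WAVE file")

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format   = readBin(fmt_raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate     = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(fmt_raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort("missing fmt or data chunk")

  bytes <- fmt$bits %/% 8
  n <- length(data_raw) %/% bytes
  x <- switch(
    as.character(fmt$format),
    "1" = { # integer PCM
      if (fmt$bits == 16) {
        readBin(data_raw, "integer", n, 2, signed = TRUE, endian = "little") / 32768
      } else if (fmt$bits == 32) {
        readBin(data_raw, "integer", n, 4, endian = "little") / 2147483648
      } else if (fmt$bits == 24) {
        m <- matrix(as.integer(data_raw), nrow = 3)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else if (fmt$bits == 8) {
        (as.integer(data_raw) - 128) / 128
      } else abort(paste0("unsupported PCM bit depth: ", fmt$bits))
    },
    "3" = readBin(data_raw, "double", n, bytes, endian = "little"),
    abort(paste0("unsupported WAV format code: ", fmt$format))
  )
  if (fmt$channels > 1) {
    x <- x[seq(1, length(x), by = fmt$channels)]
  }
  audio_clip(x, fmt$rate, clip_id %||% sub("\\.wav$", "", basename(path), ignore.case = TRUE))
}

#' Write a mono float32 RIFF/WAVE file
#'
#' @param samples Numeric amplitude vector.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(samples) * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(3L, con, 2, endian = "little")                 # IEEE float
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(round(rate)), con, 4, endian = "little")
  writeBin(as.integer(round(rate)) * 4L, con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little")
  writeBin(32L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(as.numeric(samples), con, 4, endian = "little")
  invisible(path)
}

#' Construct an audio clip
#'
#' @param samples Numeric amplitude vector (dimensionless).
#' @param rate Sampling rate in Hz (> 0).
#' @param clip_id Identifier.
#' @return An `audio_clip` object.
#' @export
audio_clip <- function(samples, rate, clip_id = "clip") {
  if (rate <= 0) abort("sampling rate must be positive")
  if (length(samples) < 1) abort("empty audio")
  structure(
    list(samples = as.numeric(samples), rate = rate, clip_id = as.character(clip_id)),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf(
    "<audio_clip '%s': %d samples @ %.3f Hz (%.3f s)>\n",
    x$clip_id, length(x$samples), x$rate, length(x$samples) / x$rate
  ))
  invisible(x)
}
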