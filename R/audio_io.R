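#' Audio clip container
#'
#' A mono audio clip: a numeric sample vector with nominal range -1..1 and a
#' sample rate in Hz.
#'
#' @param samples numeric vector of finite samples.
#' @param sample_rate sampling rate in Hz (> 0).
#' @return An object of class `audio_clip` with elements `samples` and
#'   `sample_rate`.
#' @export
audio_clip <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) == 0L)
    ms_input_error("audio_clip: 'samples' must be a non-empty numeric vector")
  if (!all(is.finite(samples)))
    ms_input_error("audio_clip: all samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    ms_input_error("audio_clip: 'sample_rate' must be a single positive number")
  structure(list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate)),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip: %d samples @ %g Hz (%.1f ms), range [%.3f, %.3f]>\n",
              length(x$samples), x$sample_rate, duration_ms(x),
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Duration of a clip in milliseconds
#' @param clip an [audio_clip()].
#' @return duration in ms (numeric).
#' @export
duration_ms <- function(clip) 1000 * length(clip$samples) / clip$sample_rate

#' Load a WAV file as a mono audio clip
#'
#' Reads a RIFF/WAVE file (PCM 16/24/32-bit or IEEE float 32/64-bit).
#' Multi-channel audio is averaged to mono; integer PCM is rescaled to
#' -1..1.
#'
#' @param path path to a WAV file.
#' @return An [audio_clip()].
#' @export
load_audio <- function(path) {
  w <- read_wav(path)
  samples <- if (is.matrix(w$samples)) rowMeans(w$samples) else w$samples
  audio_clip(samples, w$sample_rate)
}

# --- minimal RIFF/WAVE reader -------------------------------------------------
# Walks RIFF chunks, handles odd-length chunk padding, decodes the fmt and
# data chunks. Returns samples as a vector (mono) or n x channels matrix,
# already scaled to -1..1.
read_wav <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    ms_input_error("read_wav: file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 12L)
  if (length(hdr) < 12L || rawToChar(hdr[1:4]) != "RIFF" || rawToChar(hdr[9:12]) != "WAVE")
    ms_input_error("read_wav: not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    chdr <- readBin(con, "raw", 8L)
    if (length(chdr) < 8L) break
    cid <- rawToChar(chdr[1:4])
    csize <- readBin(chdr[5:8], "integer", 1L, size = 4L, endian = "little")
    if (csize < 0) ms_input_error("read_wav: corrupt chunk size in ", path)
    body <- readBin(con, "raw", csize)
    if (length(body) < csize)
      ms_input_error("read_wav: truncated chunk '", cid, "' in ", path)
    if (cid == "fmt ") {
      if (csize < 16L) ms_input_error("read_wav: malformed fmt chunk in ", path)
      fmt <- list(
        format    = readBin(body[1:2], "integer", 1L, size = 2L, signed = FALSE, endian = "little"),
        channels  = readBin(body[3:4], "integer", 1L, size = 2L, signed = FALSE, endian = "little"),
        rate      = readBin(body[5:8], "integer", 1L, size = 4L, endian = "little"),
        bits      = readBin(body[15:16], "integer", 1L, size = 2L, signed = FALSE, endian = "little"))
      if (fmt$format == 0xFFFE && csize >= 40L)  # WAVE_FORMAT_EXTENSIBLE: subformat GUID
        fmt$format <- readBin(body[25:26], "integer", 1L, size = 2L, signed = FALSE, endian = "little")
    } else if (cid == "data") {
      data_raw <- body
    }
    if (csize %% 2L == 1L) readBin(con, "raw", 1L)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw) || length(data_raw) == 0L)
    ms_input_error("read_wav: no decodable audio data in ", path)

  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% (bytes * fmt$channels)
  if (n_total == 0L) ms_input_error("read_wav: empty data chunk in ", path)
  usable <- n_total * bytes * fmt$channels
  data_raw <- data_raw[seq_len(usable)]

  x <- switch(as.character(fmt$format),
    "1" = {  # integer PCM
      if (bytes == 2L) {
        readBin(data_raw, "integer", n_total * fmt$channels, size = 2L,
                signed = TRUE, endian = "little") / 32768
      } else if (bytes == 3L) {
        m <- matrix(as.integer(data_raw), nrow = 3L)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else if (bytes == 4L) {
        readBin(data_raw, "integer", n_total * fmt$channels, size = 4L,
                endian = "little") / 2147483648
      } else if (bytes == 1L) {
        (as.integer(data_raw) - 128) / 128  # 8-bit WAV is unsigned
      } else ms_input_error("read_wav: unsupported PCM bit depth ", fmt$bits)
    },
    "3" = {  # IEEE float
      readBin(data_raw, "double", n_total * fmt$channels, size = bytes,
              endian = "little")
    },
    ms_input_error("read_wav: unsupported WAV format code ", fmt$format))

  if (fmt$channels > 1L)
    x <- matrix(x, ncol = fmt$channels, byrow = TRUE)
  list(samples = x, sample_rate = fmt$rate, bits = fmt$bits, format = fmt$format)
}

#' Write an audio clip (or multi-channel matrix) to a WAV file
#'
#' @param clip an [audio_clip()], or a numeric vector/matrix (columns =
#'   channels) with values in -1..1.
#' @param path output path.
#' @param sample_rate required when `clip` is a bare vector/matrix.
#' @param bit_depth 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, sample_rate = NULL, bit_depth = 16L) {
  if (inherits(clip, "audio_clip")) {
    x <- clip$samples
    sample_rate <- clip$sample_rate
  } else x <- clip
  if (is.null(sample_rate)) ms_input_error("write_wav: sample_rate required")
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  channels <- ncol(x)
  interleaved <- as.numeric(t(x))
  if (!bit_depth %in% c(16L, 32L))
    ms_input_error("write_wav: bit_depth must be 16 or 32")
  bytes <- bit_depth %/% 8L
  fmt_code <- if (bit_depth == 32L) 3L else 1L

  data_len <- length(interleaved) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(as.integer(channels), con, size = 2L, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * channels * bytes), con, size = 4L, endian = "little")
  writeBin(as.integer(channels * bytes), con, size = 2L, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4L, endian = "little")
  if (bit_depth == 16L) {
    q <- as.integer(pmax(-32768, pmin(32767, round(interleaved * 32767))))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(interleaved, con, size = 4L, endian = "little")
  }
  invisible(path)
}
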