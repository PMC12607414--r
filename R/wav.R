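#' Audio clips
#'
#' An `audio_clip` is a uniformly sampled mono amplitude series, nominally in
#' \[-1, 1\], plus its sample rate. It is the substrate for every acoustic
#' operation in the package.
#'
#' @param samples numeric vector of amplitudes; must be finite.
#' @param sample_rate_hz sampling rate in Hz (> 0).
#' @return an object of class `audio_clip` with elements `samples` and
#'   `sample_rate_hz`.
#' @export
audio_clip <- function(samples, sample_rate_hz) {
  samples <- as.numeric(samples)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0)
    stopf("sample_rate_hz must be a single positive number")
  if (length(samples) && any(!is.finite(samples)))
    stopf("audio samples must be finite")
  structure(list(samples = samples, sample_rate_hz = sample_rate_hz),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz))
  invisible(x)
}

#' @export
length.audio_clip <- function(x) length(x$samples)

clip_duration_s <- function(clip) length(clip$samples) / clip$sample_rate_hz

# --- RIFF/WAVE I/O -----------------------------------------------------------
# Minimal mono WAV support: integer PCM (16/24/32-bit) and IEEE float32.
# Multi-channel files are read by keeping channel 1.

#' Read a WAV file as an audio clip
#'
#' Supports integer PCM at 16/24/32 bits and 32-bit IEEE float. Stereo or
#' multi-channel input is reduced to its first channel.
#'
#' @param path path to a `.wav` file.
#' @return an [audio_clip()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stopf("not a RIFF file: %s", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stopf("not a WAVE file: %s", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2,
                               endian = "little", signed = FALSE),
        n_channels   = readBin(raw_fmt[3:4], "integer", 1, 2,
                               endian = "little", signed = FALSE),
        sample_rate  = readBin(raw_fmt[5:8], "integer", 1, 4,
                               endian = "little"),
        bits         = readBin(raw_fmt[15:16], "integer", 1, 2,
                               endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stopf("malformed WAV: data before fmt chunk")
      samples <- decode_wav_data(readBin(con, "raw", size), fmt)
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)  # skip unknown chunk (word-aligned)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stopf("no data chunk found in %s", path)
  audio_clip(samples, fmt$sample_rate)
}

decode_wav_data <- function(raw, fmt) {
  bytes <- fmt$bits / 8
  n <- length(raw) %/% (bytes * fmt$n_channels)
  if (fmt$audio_format == 3L) {          # IEEE float
    x <- readBin(raw, "double", n * fmt$n_channels, size = 4, endian = "little")
  } else if (fmt$audio_format == 1L) {   # integer PCM
    if (fmt$bits == 16) {
      x <- readBin(raw, "integer", n * fmt$n_channels, size = 2,
                   endian = "little", signed = TRUE) / 32768
    } else if (fmt$bits == 24) {
      m <- matrix(as.integer(raw[seq_len(3 * n * fmt$n_channels)]), nrow = 3)
      v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      x <- v / 8388608
    } else if (fmt$bits == 32) {
      x <- readBin(raw, "integer", n * fmt$n_channels, size = 4,
                   endian = "little") / 2147483648
    } else stopf("unsupported PCM bit depth: %d", fmt$bits)
  } else stopf("unsupported WAV audio format code: %d", fmt$audio_format)
  if (fmt$n_channels > 1) x <- x[seq(1, length(x), by = fmt$n_channels)]
  x
}

#' Write an audio clip to a WAV file
#'
#' @param clip an [audio_clip()].
#' @param path output path.
#' @param bit_depth one of `"float32"`, `"pcm16"`, `"pcm24"`. Integer formats
#'   clip amplitudes to \[-1, 1\].
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, bit_depth = c("float32", "pcm16", "pcm24")) {
  bit_depth <- match.arg(bit_depth)
  x <- clip$samples
  sr <- as.integer(round(clip$sample_rate_hz))
  enc <- switch(bit_depth,
    float32 = list(fmt = 3L, bits = 32L,
                   data = writeBin(as.numeric(x), raw(), size = 4,
                                   endian = "little")),
    pcm16 = list(fmt = 1L, bits = 16L,
                 data = writeBin(as.integer(pmax(-32768, pmin(32767,
                        round(x * 32768)))), raw(), size = 2,
                        endian = "little")),
    pcm24 = {
      v <- as.integer(pmax(-8388608, pmin(8388607, round(x * 8388608))))
      v <- ifelse(v < 0, v + 16777216L, v)
      b <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
      list(fmt = 1L, bits = 24L, data = as.raw(b))
    })
  bytes_per <- enc$bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(enc$data)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(enc$fmt, 1L), con, size = 2, endian = "little")        # format, mono
  writeBin(as.integer(c(sr, sr * bytes_per)), con, size = 4, endian = "little")
  writeBin(as.integer(c(bytes_per, enc$bits)), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(enc$data)), con, size = 4, endian = "little")
  writeBin(enc$data, con)
  invisible(path)
}
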