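# Minimal RIFF/PCM WAV reader and writer (readBin/writeBin). The writer
# emits the canonical 44-byte-header, 16-bit little-endian PCM layout the
# telemetry schema assumes; the reader additionally accepts 8/32-bit integer
# and 32-bit float PCM at any rate/channel count so foreign recordings can be
# standardized. Amplitude convention: sample k maps to k/32767, so values on
# the 16-bit grid round-trip exactly.

WAV_FULL_SCALE <- 32767

#' Serialize samples to WAV bytes
#'
#' @param samples Numeric vector (mono) or matrix with one column per
#'   channel, amplitudes in \[-1, 1\].
#' @param rate Sample rate in Hz.
#' @return Raw vector: a complete RIFF/WAVE file (16-bit PCM).
#' @export
wav_bytes <- function(samples, rate = 16000) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  n_ch <- ncol(samples)
  pcm <- as.integer(round(clamp(t(samples), -1, 1) * WAV_FULL_SCALE))
  block_align <- n_ch * 2L
  data_size <- length(pcm) * 2L
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * block_align), con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  rawConnectionValue(con)
}

#' Write a WAV file
#'
#' @param samples Numeric vector or channel-column matrix in \[-1, 1\], or an
#'   `audio_clip`.
#' @param path Output path.
#' @param rate Sample rate (Hz); taken from the clip if one is given.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, rate = 16000) {
  if (inherits(samples, "audio_clip")) {
    rate <- samples$rate
    samples <- samples$samples
  }
  writeBin(wav_bytes(samples, rate), path)
  invisible(path)
}

#' Read a WAV file
#'
#' Accepts 8/16/32-bit integer and 32-bit IEEE float PCM, any rate and
#' channel count.
#'
#' @param path Path to a RIFF/WAVE file (or a raw vector of WAV bytes).
#' @return `list(samples, rate, bits, channels)` where `samples` is a matrix
#'   with one column per channel, amplitudes in \[-1, 1\].
#' @export
read_wav <- function(path) {
  con <- if (is.raw(path)) rawConnection(path, "rb") else file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stopf("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stopf("not a WAVE file")
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      body <- readBin(con, raw(), n = size)
      fmt <- list(
        format = readBin(body[1:2], integer(), size = 2, endian = "little"),
        channels = readBin(body[3:4], integer(), size = 2, endian = "little"),
        rate = readBin(body[5:8], integer(), size = 4, endian = "little"),
        bits = readBin(body[15:16], integer(), size = 2, endian = "little")
      )
    } else if (id == "data") {
      data_raw <- readBin(con, raw(), n = size)
    } else {
      invisible(readBin(con, raw(), n = size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stopf("missing fmt/data chunk")
  x <- decode_pcm(data_raw, fmt)
  list(samples = matrix(x, ncol = fmt$channels, byrow = TRUE),
       rate = fmt$rate, bits = fmt$bits, channels = fmt$channels)
}

decode_pcm <- function(data_raw, fmt) {
  n <- length(data_raw) %/% (fmt$bits %/% 8L)
  if (fmt$format == 1L) {
    switch(
      as.character(fmt$bits),
      "8" = (readBin(data_raw, integer(), n = n, size = 1,
                     signed = FALSE) - 128) / 128,
      "16" = readBin(data_raw, integer(), n = n, size = 2,
                     endian = "little") / WAV_FULL_SCALE,
      "32" = readBin(data_raw, integer(), n = n, size = 4,
                     endian = "little") / 2147483647,
      stopf("unsupported PCM bit depth: %d", fmt$bits)
    )
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data_raw, numeric(), n = n, size = 4, endian = "little")
  } else {
    stopf("unsupported WAV format code %d (%d-bit)", fmt$format, fmt$bits)
  }
}
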