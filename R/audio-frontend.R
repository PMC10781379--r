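# Deterministic audio front end: clip standardization (16 kHz / mono / fixed
# duration), the pre-normalization silence gate, the 129-bin magnitude
# spectrogram, and the resize + per-sample standardization stages that
# produce the classifier's 129x124 input.

#' Audio clip container
#'
#' A fixed-duration mono waveform at 16 kHz — the unit of classification.
#'
#' @param samples Numeric amplitudes in \[-1, 1\].
#' @param rate Sample rate (Hz).
#' @return An object of class `audio_clip` with fields `samples`, `rate`,
#'   `duration`.
#' @export
audio_clip <- function(samples, rate = 16000) {
  structure(list(samples = as.numeric(samples), rate = rate,
                 duration = length(samples) / rate),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("audio clip: %.3f s @ %d Hz (%d samples, peak %.3f)\n",
              x$duration, x$rate, length(x$samples),
              max(abs(x$samples))))
  invisible(x)
}

#' Standardize raw audio to the model's clip format
#'
#' Mixes to mono (channel mean), resamples to 16 kHz, right-trims or
#' zero-pads to the target duration, and clamps amplitudes to \[-1, 1\]. A
#' clip that already conforms is returned unchanged bit-for-bit.
#'
#' @param x An `audio_clip`, a numeric vector, a channel-column matrix, or
#'   the list returned by [read_wav()].
#' @param rate Sample rate of `x` (ignored when `x` carries its own).
#' @param target_duration Clip duration in seconds (1 or 2 by convention).
#' @param target_rate Output rate (Hz).
#' @return An `audio_clip` of exactly `target_rate * target_duration`
#'   samples.
#' @export
#' @examples
#' clip <- standardize_clip(sin(2 * pi * 440 * seq(0, 2, by = 1 / 44100)),
#'                          rate = 44100, target_duration = 2)
#' length(clip$samples)  # 32000
standardize_clip <- function(x, rate = 16000, target_duration = 1,
                             target_rate = 16000) {
  if (inherits(x, "audio_clip")) {
    rate <- x$rate
    x <- x$samples
  } else if (is.list(x) && !is.null(x$samples)) {
    rate <- x$rate
    x <- x$samples
  }
  if (!is.null(dim(x))) x <- rowMeans(x)
  x <- as.numeric(x)
  if (length(x) == 0 || all(is.na(x))) stopf("empty or all-NaN audio input")
  n_target <- as.integer(round(target_rate * target_duration))
  if (rate == target_rate && length(x) == n_target && max(abs(x)) <= 1) {
    return(audio_clip(x, target_rate))  # idempotence fast path
  }
  if (rate != target_rate) {
    g <- gcd_int(target_rate, rate)
    x <- as.numeric(signal::resample(x, target_rate %/% g, rate %/% g))
  }
  if (length(x) >= n_target) {
    x <- x[seq_len(n_target)]
  } else {
    x <- c(x, numeric(n_target - length(x)))
  }
  audio_clip(clamp(x, -1, 1), target_rate)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Pre-normalization silence gate
#'
#' `TRUE` (silence: skip inference) iff the RMS of the *raw* samples is
#' strictly below `threshold` times full scale. The gate must run before any
#' amplitude normalization — normalizing first rescales quiet clips to full
#' amplitude and makes an energy gate useless.
#'
#' @param clip An `audio_clip` (standardized, not yet normalized).
#' @param threshold Fraction of full scale (default 0.01).
#' @return Logical: `TRUE` when the clip should be skipped as silence.
#' @export
silence_gate <- function(clip, threshold = 0.01) {
  sqrt(mean(clip$samples^2)) < threshold
}

#' Peak-normalize a clip to \[-1, 1\]
#'
#' Applied after the silence gate, before the spectrogram. All-zero clips
#' are returned unchanged.
#'
#' @param clip An `audio_clip`.
#' @return The normalized `audio_clip`.
#' @export
normalize_peak <- function(clip) {
  m <- max(abs(clip$samples))
  if (m > 0) clip$samples <- clip$samples / m
  clip
}

#' Front-end configuration
#'
#' Short-time transform parameters: 256-point FFT with a 256-sample periodic
#' Hann window, hop 100 samples, and end-padding so the frame count is
#' `ceil(N / hop)` — at 16 kHz this yields 129 frequency bins (62.5 Hz
#' spacing) and 160 frames per 1 s clip.
#'
#' @param nfft FFT length.
#' @param window_length Analysis window length (<= `nfft`).
#' @param hop Hop size in samples.
#' @param silence_rms_threshold Default silence-gate threshold.
#' @return An object of class `frontend_config`.
#' @export
frontend_config <- function(nfft = 256L, window_length = 256L, hop = 100L,
                            silence_rms_threshold = 0.01) {
  if (nfft < window_length) stopf("nfft must be >= window length")
  if (hop <= 0) stopf("hop must be positive")
  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, window_length - 1L) / window_length)
  structure(list(nfft = as.integer(nfft),
                 window_length = as.integer(window_length),
                 window = w, hop = as.integer(hop),
                 silence_rms_threshold = silence_rms_threshold),
            class = "frontend_config")
}

#' Magnitude spectrogram of a clip
#'
#' One-sided short-time magnitude transform with end-padding: frame `t`
#' (0-based) covers samples starting at `t * hop`, zero-padded past the clip
#' end, for `ceil(N / hop)` frames in total.
#'
#' @param clip A standardized (and, in the classification pipeline,
#'   peak-normalized) `audio_clip`.
#' @param cfg A [frontend_config()].
#' @return `spectrogram`: a `(nfft/2 + 1) x frames` non-negative matrix with
#'   attributes `bin_hz` (62.5) and `hop_s`.
#' @export
#' @examples
#' sp <- compute_spectrogram(audio_clip(sin(2 * pi * 1000 * (0:15999) / 16000)))
#' dim(sp)  # 129 160
compute_spectrogram <- function(clip, cfg = frontend_config()) {
  x <- clip$samples
  n <- length(x)
  if (n < cfg$window_length) stopf("clip shorter than one analysis window")
  frames <- as.integer(ceiling(n / cfg$hop))
  padded <- c(x, numeric((frames - 1L) * cfg$hop + cfg$nfft - n))
  starts <- (seq_len(frames) - 1L) * cfg$hop
  fm <- vapply(starts,
               function(s) padded[(s + 1L):(s + cfg$window_length)] * cfg$window,
               numeric(cfg$window_length))
  if (cfg$nfft > cfg$window_length) {
    fm <- rbind(fm, matrix(0, cfg$nfft - cfg$window_length, frames))
  }
  mags <- Mod(stats::mvfft(fm))[seq_len(cfg$nfft %/% 2L + 1L), , drop = FALSE]
  structure(mags, bin_hz = clip$rate / cfg$nfft, hop_s = cfg$hop / clip$rate,
            class = c("spectrogram", "matrix"))
}

# Bilinear (linear along time) resize with half-pixel centers, corner
# alignment off: output column j (0-based) samples input position
# (j + 0.5) * T_in / T_out - 0.5.
resize_time_axis <- function(m, width_out) {
  t_in <- ncol(m)
  if (t_in == width_out) return(m)
  xc <- (seq_len(width_out) - 0.5) * t_in / width_out - 0.5
  i0 <- clamp(floor(xc), 0, t_in - 1L)
  i1 <- clamp(i0 + 1, 0, t_in - 1L)
  frac <- clamp(xc - i0, 0, 1)
  out <- m[, i0 + 1L, drop = FALSE] * rep(1 - frac, each = nrow(m)) +
    m[, i1 + 1L, drop = FALSE] * rep(frac, each = nrow(m))
  out
}

#' Prepare the classifier input from a spectrogram
#'
#' The two fixed preprocessing stages in front of the network: a resizing
#' stage that brings the time axis to `width` columns (bilinear, half-pixel
#' centers), followed by per-sample standardization
#' `(x - mean(x)) / max(sd(x), 1e-6)` over all pixels of the sample. A
#' constant spectrogram therefore maps to an all-zero input.
#'
#' @param spec A [compute_spectrogram()] result (129 rows).
#' @param width Output time-axis width (124).
#' @return `model_input`: a standardized `129 x width` matrix.
#' @export
prepare_model_input <- function(spec, width = 124L) {
  if (nrow(spec) != 129L) {
    stopf("expected 129 frequency rows, got %d", nrow(spec))
  }
  m <- resize_time_axis(unclass(spec), width)
  mu <- mean(m)
  sdv <- sqrt(mean((m - mu)^2))
  structure((m - mu) / max(sdv, 1e-6), class = c("model_input", "matrix"))
}

#' Full front-end pipeline for one clip
#'
#' Standardize -> silence gate -> peak normalization -> spectrogram ->
#' model input. Returns `NULL` when the gate flags the clip as silence.
#'
#' @param clip An `audio_clip` (already standardized) or raw audio accepted
#'   by [standardize_clip()].
#' @param cfg A [frontend_config()].
#' @param gate Apply the silence gate (`TRUE` in streaming use; training
#'   pipelines keep every labelled clip).
#' @return A `model_input`, or `NULL` for gated silence.
#' @export
frontend_pipeline <- function(clip, cfg = frontend_config(), gate = TRUE) {
  if (!inherits(clip, "audio_clip")) clip <- standardize_clip(clip)
  if (gate && silence_gate(clip, cfg$silence_rms_threshold)) return(NULL)
  prepare_model_input(compute_spectrogram(normalize_peak(clip), cfg))
}

#' Export a spectrogram (or any matrix) to CSV
#'
#' Plain rectangular CSV, rows = frequency bins (row 1 = 0 Hz), columns =
#' time frames.
#'
#' @param m Matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
spectrogram_to_csv <- function(m, path) {
  utils::write.table(unclass(m), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
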