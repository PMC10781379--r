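# Seeded synthetic-audio generator for the five sound classes the classifier
# distinguishes, plus the dataset manifest builder with a 70/20/10
# train/validation/test split. The signal models are intentionally simple and
# parametric: they stand in for real recordings and are designed to make the
# classes statistically distinguishable, not to sound realistic.

#' The five default sound classes
#'
#' @return Character vector: cough, other, music, conversation, ambient.
#' @export
cough_classes <- function() {
  c("cough", "other", "music", "conversation", "ambient")
}

#' Synthesize one labelled clip
#'
#' Deterministic per `(label, seed)`. Signal models:
#' * `cough` — one or two exponentially decaying broadband bursts
#'   (80-300 ms), band-emphasized 300-3000 Hz;
#' * `other` — transients or tones that violate the cough envelope (click
#'   trains, steady tones, chirps);
#' * `music` — a harmonic note sequence with note changes;
#' * `conversation` — 3-6 Hz amplitude-modulated band-limited noise shaped
#'   by one of two formant presets (lower/higher voice);
#' * `ambient` — low-level 1/f noise.
#'
#' Samples are quantized to the 16-bit grid so WAV round trips are exact.
#'
#' @param label One of [cough_classes()].
#' @param seed Integer seed.
#' @param duration Clip length in seconds (1 or 2).
#' @return An `audio_clip` of `16000 * duration` samples.
#' @export
#' @examples
#' clip <- synth_clip("cough", seed = 7)
#' max(abs(clip$samples)) <= 1
synth_clip <- function(label, seed = 1L, duration = 1.0) {
  if (!duration %in% c(1.0, 2.0)) stopf("duration must be 1 or 2 seconds")
  classes <- cough_classes()
  if (!label %in% classes) stopf("unknown label '%s'", label)
  rate <- 16000L
  n <- as.integer(rate * duration)
  x <- with_local_seed(
    mix_seed(seed, match(label, classes)),
    switch(label,
           cough = synth_cough(n, rate),
           other = synth_other(n, rate),
           music = synth_music(n, rate),
           conversation = synth_conversation(n, rate),
           ambient = synth_ambient(n, rate))
  )
  x <- clamp(x, -1, 1)
  audio_clip(round(x * WAV_FULL_SCALE) / WAV_FULL_SCALE, rate)
}

# --- class signal models (run under a local seed) ---

bandpass_noise <- function(n, rate, low, high) {
  bf <- signal::butter(4, c(low, high) / (rate / 2), type = "pass")
  as.numeric(signal::filter(bf, stats::rnorm(n)))
}

synth_cough <- function(n, rate) {
  x <- numeric(n)
  n_bursts <- 1L + (stats::runif(1) < 0.4)
  t0 <- stats::runif(1, 0.05, 0.35)
  for (b in seq_len(n_bursts)) {
    dur <- stats::runif(1, 0.08, 0.30)
    len <- as.integer(dur * rate)
    start <- as.integer(t0 * rate) + 1L
    if (start + len - 1L > n) len <- n - start + 1L
    if (len < 64L) break
    tt <- seq_len(len) / rate
    attack <- 1 - exp(-tt / 0.004)
    decay <- exp(-tt / (dur / 3))
    burst <- bandpass_noise(len, rate, 300, 3000) * attack * decay
    peak <- stats::runif(1, 0.6, 0.95)
    burst <- burst / max(abs(burst)) * peak
    x[start:(start + len - 1L)] <- x[start:(start + len - 1L)] + burst
    t0 <- t0 + dur + stats::runif(1, 0.10, 0.30)
  }
  x
}

synth_other <- function(n, rate) {
  type <- sample(c("clicks", "tone", "chirp"), 1)
  tt <- seq_len(n) / rate
  if (type == "clicks") {
    x <- numeric(n)
    for (k in seq_len(sample(3:8, 1))) {
      len <- as.integer(stats::runif(1, 0.002, 0.008) * rate)
      start <- sample.int(n - len, 1)
      x[start:(start + len - 1L)] <- stats::rnorm(len) *
        stats::runif(1, 0.5, 0.9)
    }
    x
  } else if (type == "tone") {
    f <- stats::runif(1, 200, 6000)
    sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi)) *
      stats::runif(1, 0.3, 0.6)
  } else {
    f0 <- stats::runif(1, 150, 400)
    f1 <- stats::runif(1, 2500, 5000)
    phase <- 2 * pi * (f0 * tt + (f1 - f0) * tt^2 / (2 * max(tt)))
    sin(phase) * stats::runif(1, 0.35, 0.6)
  }
}

synth_music <- function(n, rate) {
  # pentatonic pool over two octaves; 4-8 notes with smooth onsets
  pool <- 220 * 2^(c(0, 2, 4, 7, 9, 12, 14, 16, 19, 21) / 12)
  k <- sample(4:8, 1)
  note_len <- n %/% k
  x <- numeric(n)
  for (j in seq_len(k)) {
    f <- sample(pool, 1)
    len <- if (j < k) note_len else n - note_len * (k - 1L)
    tt <- seq_len(len) / rate
    env <- sin(pi * seq_len(len) / len)^0.7
    note <- numeric(len)
    for (h in 1:3) {
      note <- note + sin(2 * pi * f * h * tt + stats::runif(1, 0, 2 * pi)) / h
    }
    x[(note_len * (j - 1L) + 1L):(note_len * (j - 1L) + len)] <- note * env
  }
  x / max(abs(x)) * stats::runif(1, 0.4, 0.6)
}

synth_conversation <- function(n, rate) {
  # two voice presets (approximately even mix): formant center frequencies
  preset <- sample(1:2, 1)
  formants <- if (preset == 1) c(450, 1400) else c(650, 2100)
  src <- bandpass_noise(n, rate, 100, 4000)
  x <- numeric(n)
  for (fc in formants) {
    r <- 0.97
    w <- 2 * pi * fc / rate
    x <- x + as.numeric(signal::filter(1, c(1, -2 * r * cos(w), r^2), src))
  }
  tt <- seq_len(n) / rate
  fm <- stats::runif(1, 3, 6)  # syllabic amplitude modulation
  mod <- (0.5 * (1 + sin(2 * pi * fm * tt + stats::runif(1, 0, 2 * pi))))^1.3
  x <- x * (0.1 + 0.9 * mod)
  x / max(abs(x)) * stats::runif(1, 0.35, 0.55)
}

synth_ambient <- function(n, rate) {
  # 1/f ("pink") noise via spectral shaping, low level but above the gate
  half <- n %/% 2L
  mag <- c(0, 1 / sqrt(seq_len(half)))
  phase <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = 0, argument = 0, length.out = n)
  spec[2:(half + 1L)] <- mag[-1] * exp(1i * phase)
  spec[n - seq_len(half - 1L) + 1L] <- Conj(spec[2:half])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / sqrt(mean(x^2)) * stats::runif(1, 0.03, 0.05)
}

#' Compose a longer audio stream from labelled events over an ambient bed
#'
#' Builds a continuous 16 kHz stream: low-level ambient noise for the whole
#' duration, with 1 s labelled clips (coughs, speech, ...) mixed in at the
#' requested times. Used to exercise streaming detection and the monitor.
#'
#' @param duration Stream length (s).
#' @param events Data frame with columns `label` and `time` (onset, s), or
#'   `NULL` for pure ambient.
#' @param seed Integer seed.
#' @param ambient_level Peak scale of the ambient bed (0 disables it, giving
#'   silence between events).
#' @return An `audio_clip` of `16000 * duration` samples.
#' @export
#' @examples
#' st <- synth_stream(10, data.frame(label = "cough", time = 2.0), seed = 5)
synth_stream <- function(duration, events = NULL, seed = 1L,
                         ambient_level = 1.0) {
  rate <- 16000L
  n <- as.integer(rate * duration)
  bed <- if (ambient_level > 0) {
    with_local_seed(mix_seed(seed, 999L), synth_ambient(n, rate)) *
      ambient_level
  } else {
    numeric(n)
  }
  if (!is.null(events)) {
    for (i in seq_len(nrow(events))) {
      clip <- synth_clip(events$label[i], mix_seed(seed, i), 1.0)
      s0 <- as.integer(events$time[i] * rate) + 1L
      idx <- s0:min(n, s0 + length(clip$samples) - 1L)
      bed[idx] <- bed[idx] + clip$samples[seq_along(idx)]
    }
  }
  audio_clip(clamp(bed, -1, 1), rate)
}

# --- band-energy features + analytic baseline classifier ---

#' Band-energy and envelope features of a clip
#'
#' The simple analytic features the synthetic classes are built to separate:
#' fraction of spectral energy in the 300-3000 Hz cough band, kurtosis of
#' the amplitude envelope (burstiness), and log RMS level.
#'
#' @param clip An `audio_clip`.
#' @return Named numeric vector `band_ratio`, `env_kurtosis`, `log_rms`.
#' @export
band_energy_features <- function(clip) {
  x <- clip$samples
  n <- length(x)
  p <- Mod(stats::fft(x))[seq_len(n %/% 2L + 1L)]^2
  freqs <- (seq_along(p) - 1L) * clip$rate / n
  band <- freqs >= 300 & freqs <= 3000
  env <- stats::filter(abs(x), rep(1 / 160, 160), sides = 2)
  env <- env[!is.na(env)]
  mu <- mean(env); s <- stats::sd(env)
  kur <- if (s > 0) mean((env - mu)^4) / s^4 else 3
  c(band_ratio = sum(p[band]) / sum(p),
    env_kurtosis = kur,
    log_rms = log10(sqrt(mean(x^2)) + 1e-12))
}

#' Fit the analytic band-energy baseline classifier
#'
#' Nearest-centroid classifier on z-scored [band_energy_features()]. It is
#' the yardstick the convolutional model must beat, and doubles as the check
#' that the synthetic classes are separable by construction.
#'
#' @param clips List of `audio_clip`s.
#' @param labels Character/factor labels, one per clip.
#' @return An object of class `band_energy_baseline`.
#' @export
fit_band_energy_baseline <- function(clips, labels) {
  feats <- t(vapply(clips, band_energy_features, numeric(3)))
  mu <- colMeans(feats)
  sdv <- apply(feats, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(feats, 2, mu), 2, sdv, "/")
  labels <- as.character(labels)
  centroids <- do.call(rbind, lapply(split(seq_along(labels), labels),
                                     function(i) colMeans(z[i, , drop = FALSE])))
  structure(list(centroids = centroids, mu = mu, sd = sdv),
            class = "band_energy_baseline")
}

#' @export
predict.band_energy_baseline <- function(object, clips, ...) {
  feats <- t(vapply(clips, band_energy_features, numeric(3)))
  z <- sweep(sweep(feats, 2, object$mu), 2, object$sd, "/")
  d2 <- outer(rowSums(z^2), rowSums(object$centroids^2), "+") -
    2 * z %*% t(object$centroids)
  rownames(object$centroids)[apply(d2, 1, which.min)]
}

# --- dataset builder ---

# Largest-remainder allocation of n items to the given weights.
allocate_largest_remainder <- function(n, weights) {
  exact <- n * weights / sum(weights)
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Build a labelled synthetic dataset with a 70/20/10 split
#'
#' Allocates clips per class (balanced by default, largest-remainder when
#' `n_total` is not divisible), assigns each class's clips to
#' train/validation/test by a seeded shuffle with largest-remainder split
#' counts, and optionally synthesizes and writes the clips as WAV files.
#'
#' @param n_total Total number of clips (>= number of classes).
#' @param labels Class labels (default the five standard classes).
#' @param balanced Equal per-class counts (largest remainder otherwise of
#'   the class weights implied by `labels`).
#' @param split Length-3 percentages for train/validation/test.
#' @param seed Integer seed controlling split assignment and clip seeds.
#' @param duration Clip duration (s).
#' @param dir Output directory for WAV files and `manifest.csv`; `NULL`
#'   builds the manifest only (clips are then synthesized on demand from
#'   their recorded seeds).
#' @return A `dataset_manifest`: data frame with columns `clip_id`, `label`,
#'   `split`, `seed`, `path`, with per-class/per-split totals in
#'   `attr(, "totals")`.
#' @export
#' @examples
#' m <- build_dataset(50, seed = 1)
#' table(m$label, m$split)
build_dataset <- function(n_total, labels = cough_classes(), balanced = TRUE,
                          split = c(70, 20, 10), seed = 1L, duration = 1.0,
                          dir = NULL) {
  if (n_total < length(labels)) stopf("n_total smaller than the class count")
  if (length(split) != 3 || any(split < 0)) stopf("split must be 3 percentages")
  class_counts <- allocate_largest_remainder(n_total, rep(1, length(labels)))
  names(class_counts) <- labels
  rows <- list()
  for (ci in seq_along(labels)) {
    lab <- labels[ci]
    n_c <- class_counts[ci]
    split_counts <- allocate_largest_remainder(n_c, split)
    assignment <- rep(c("train", "val", "test"), times = split_counts)
    assignment <- with_local_seed(mix_seed(seed, ci, 1L),
                                  sample(assignment, n_c))
    rows[[ci]] <- data.frame(
      clip_id = sprintf("%s_%05d", lab, seq_len(n_c)),
      label = lab,
      split = assignment,
      seed = vapply(seq_len(n_c), function(i) mix_seed(seed, ci, 100L + i),
                    integer(1)),
      path = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(dir, paste0(manifest$clip_id, ".wav"))
    for (i in seq_len(nrow(manifest))) {
      write_wav(synth_clip(manifest$label[i], manifest$seed[i], duration),
                manifest$path[i])
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  attr(manifest, "duration") <- duration
  attr(manifest, "totals") <- table(manifest$label, manifest$split)
  class(manifest) <- c("dataset_manifest", class(manifest))
  manifest
}

#' Materialize the clips of a manifest
#'
#' Reads each clip from its WAV path when present, otherwise re-synthesizes
#' it from its recorded `(label, seed)` — both routes give identical
#' waveforms because generated WAVs round-trip exactly.
#'
#' @param manifest A [build_dataset()] manifest (optionally subset).
#' @param split Optional split name to filter on.
#' @return `list(clips, labels)`.
#' @export
manifest_clips <- function(manifest, split = NULL) {
  if (!is.null(split)) manifest <- manifest[manifest$split == split, ]
  duration <- attr(manifest, "duration") %||% 1.0
  clips <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!is.na(p) && file.exists(p)) {
      standardize_clip(read_wav(p), target_duration = duration)
    } else {
      synth_clip(manifest$label[i], manifest$seed[i], duration)
    }
  })
  list(clips = clips, labels = manifest$label)
}
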