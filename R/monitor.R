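# Integrated monitor: one warm-up calibration, then per-frame temperature
# measurement with fever-rule debouncing and streaming cough detection over
# the simultaneous audio track, all emitted through the telemetry layer (or
# logged locally when no server is available).

#' Monitor configuration
#'
#' @param fever_threshold Fever rule threshold (degC); a thermal packet is
#'   emitted when the corrected temperature is strictly above it.
#' @param rearm_delta Hysteresis (degC): after a thermal packet, the rule is
#'   re-armed once the temperature drops below `threshold - rearm_delta`,
#'   so one packet is emitted per above-threshold episode.
#' @param setpoints Low/high Peltier reference setpoints (degC), distinct.
#' @param frame_period Thermal frame period (s).
#' @param window,hop Audio analysis window and hop (s).
#' @param gate_threshold Silence-gate RMS threshold.
#' @param udp_port Server-discovery UDP port.
#' @param discovery_timeout Seconds to wait for an announcement.
#' @param epoch_base Epoch seconds assigned to monitor time 0 (fixed for
#'   reproducible event logs).
#' @param seed Simulation seed.
#' @return An object of class `monitor_config`.
#' @export
monitor_config <- function(fever_threshold = 38.0, rearm_delta = 0.2,
                           setpoints = c(33.0, 38.0), frame_period = 1,
                           window = 1.0, hop = 0.5, gate_threshold = 0.01,
                           udp_port = 5005L, discovery_timeout = 2,
                           epoch_base = 1700000000L, seed = 1L) {
  if (setpoints[1] == setpoints[2]) stopf("setpoints must be distinct")
  if (fever_threshold < 30 || fever_threshold > 42) {
    stopf("fever threshold outside the sensor's working range")
  }
  structure(list(fever_threshold = fever_threshold,
                 rearm_delta = rearm_delta, setpoints = setpoints,
                 frame_period = frame_period, window = window, hop = hop,
                 gate_threshold = gate_threshold,
                 udp_port = as.integer(udp_port),
                 discovery_timeout = discovery_timeout,
                 epoch_base = as.integer(epoch_base),
                 seed = as.integer(seed)),
            class = "monitor_config")
}

#' Read / write a monitor configuration file
#'
#' Flat key-value YAML; unknown keys are rejected.
#'
#' @param path Config file path.
#' @return [monitor_config()] for `read_monitor_config()`; `path` invisibly
#'   for `write_monitor_config()`.
#' @export
read_monitor_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(monitor_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stopf("unknown config keys: %s",
                             paste(bad, collapse = ", "))
  do.call(monitor_config, vals)
}

#' @rdname read_monitor_config
#' @param cfg A `monitor_config`.
#' @export
write_monitor_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the integrated monitor over scripted sources
#'
#' Performs the warm-up calibration once (reference self-detection), then
#' measures every thermal frame and runs streaming cough detection over the
#' simultaneous audio track. Thermal packets follow the fever rule with
#' hysteresis (one packet per above-threshold episode); cough packets embed
#' the detected window's audio. Every packet is delivered through `sink`
#' when one is given (online mode) and always appears in the returned event
#' log, so no detection is silently dropped.
#'
#' @param cfg A [monitor_config()].
#' @param warmup_frames Warm-up frame sequence (from [simulate_warmup()] or
#'   recorded fixtures).
#' @param frames Measurement frames (list of `thermal_frame`s); frame `i` is
#'   taken at monitor time `i * frame_period`.
#' @param audio Numeric 16 kHz stream recorded over the same span, or
#'   `NULL` for a thermal-only run.
#' @param model A trained `cough_cnn` (required when `audio` is given).
#' @param identity Device identity for packets.
#' @param sink `NULL` (offline: log only) or a function called with each
#'   emitted `event_packet` (e.g. wrapping [send_event()]).
#' @param refs Optional `c(low, high)` reference thermometer readings;
#'   defaults to the warm-up scene's plant temperatures when available,
#'   otherwise the configured setpoints.
#' @return `list(log, packets, readings)`: `log` is one row per detection
#'   opportunity (`time`, `type`, `value`, `emitted`), `packets` the emitted
#'   packets in time order, `readings` the corrected per-frame temperatures.
#' @export
run_monitor <- function(cfg, warmup_frames, frames, audio = NULL,
                        model = NULL,
                        identity = make_device_id("E", "00:00:00:00:12:34"),
                        sink = NULL, refs = NULL) {
  if (is.null(refs)) {
    sc <- attr(warmup_frames, "scene")
    refs <- if (!is.null(sc)) reference_readings(sc)
            else c(low = cfg$setpoints[1], high = cfg$setpoints[2])
  }
  regions <- tryCatch(
    detect_peltier_regions(warmup_frames, refs[[1]], refs[[2]]),
    error = function(e) stopf("calibration failed: %s", conditionMessage(e))
  )
  log_rows <- list()
  packets <- list()
  emit <- function(packet, t_mon, type, value) {
    emitted <- !is.null(packet)
    if (emitted) {
      packets[[length(packets) + 1L]] <<- packet
      if (!is.null(sink)) sink(packet)
    }
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      time = cfg$epoch_base + t_mon, type = type, value = value,
      emitted = emitted)
  }

  # thermal path: one packet per above-threshold episode (hysteresis)
  armed <- TRUE
  readings <- numeric(length(frames))
  for (i in seq_along(frames)) {
    t_mon <- i * cfg$frame_period
    reading <- measure_patient(frames[[i]], regions)
    readings[i] <- reading$corrected
    pkt <- NULL
    if (armed && reading$corrected > cfg$fever_threshold) {
      pkt <- build_thermal_event(identity, reading,
                                 threshold = cfg$fever_threshold,
                                 time = cfg$epoch_base + t_mon)
      armed <- FALSE
    } else if (!armed &&
               reading$corrected < cfg$fever_threshold - cfg$rearm_delta) {
      armed <- TRUE
    }
    emit(pkt, t_mon, "thermal", reading$corrected)
  }

  # audio path: streaming windows, merged cough events
  if (!is.null(audio)) {
    if (is.null(model)) stopf("an audio stream needs a trained model")
    events <- classify_stream(audio, model, window = cfg$window,
                              hop = cfg$hop,
                              gate_threshold = cfg$gate_threshold)
    rate <- 16000L
    for (j in seq_len(nrow(events))) {
      s0 <- as.integer(events$start[j] * rate) + 1L
      s1 <- min(length(audio), as.integer(events$end[j] * rate))
      clip <- standardize_clip(audio[s0:s1], rate = rate,
                               target_duration = 1)
      pkt <- build_cough_event(identity, clip,
                               time = cfg$epoch_base +
                                 as.integer(round(events$start[j])))
      emit(pkt, events$start[j], "cough", events$confidence[j])
    }
  }

  log <- if (length(log_rows) > 0) do.call(rbind, log_rows)
         else data.frame(time = numeric(0), type = character(0),
                         value = numeric(0), emitted = logical(0))
  ord <- order(log$time)
  log <- log[ord, ]
  rownames(log) <- NULL
  times <- vapply(packets, function(p) p$time, numeric(1))
  packets <- packets[order(times)]
  list(log = log, packets = packets, readings = readings)
}
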