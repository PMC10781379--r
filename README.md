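# feverwatch

Non-contact fever and cough monitoring, fully simulated and testable without
hardware: a self-calibrating thermopile temperature-measurement method, a
spectrogram-based cough classifier trained on synthetic audio, and the
JSON/TCP/UDP event telemetry that binds them into one monitor.

## Who this is for

Engineers and researchers building low-cost contactless screening devices
(thermopile imager + microphone on an embedded board) who need the whole
signal path — thermal calibration, audio classification, event transport —
as reproducible, seedable software before any hardware exists. Every stage
runs against bundled simulators: a physics-based thermal scene generator and
a five-class synthetic sound generator stand in for the sensor and the
training corpus.

## The methods

**Two-point thermal self-calibration.** A 24×32 thermopile views two Peltier
reference elements regulated by PID control to T_lo = 33 °C and
T_hi = 38 °C — the temperatures bracketing the clinically interesting range.
The references are located automatically from warm-up fluctuations (only
they change temperature during warm-up). For each measurement, with raw
region means r_lo, r_hi and reference-thermometer readings T_lo, T_hi, the
affine correction

    T = a·r + b,   a = (T_hi − T_lo) / (r_hi − r_lo),   b = T_lo − a·r_lo

is exact at both anchors, so any gain/offset sensor error cancels inside the
calibrated range. The patient is the hottest pixel outside the (dilated)
reference regions; its 3×3 neighbourhood mean is corrected through the
line. A packet is emitted only when the corrected temperature is strictly
above 38.0 °C, with hysteresis so one packet marks one febrile episode.

**Spectrogram cough classification.** Clips are standardized to 16 kHz mono
(1 s = 16,000 samples; 2 s = 32,000), silence-gated on *raw* amplitude
(gating after normalization is a known failure mode: normalization rescales
quiet clips to full amplitude), peak-normalized, and transformed to a
129×160 magnitude spectrogram (256-point FFT/window, hop 100, 62.5 Hz bins).
Two fixed stages resize to 129×124 and standardize per sample; a small CNN
(conv 16 → pool → conv 32 → pool → dropout → dense 64 → softmax over
{cough, other, music, conversation, ambient}) classifies each input.
Streaming audio is scanned with 1 s windows at 50 % overlap and consecutive
cough windows are merged, so coughs that straddle a window boundary are
still one event.

**Telemetry.** Events are single JSON lines over TCP —
`{"id":"E-1234","time":<epoch s>,"type":"thermal","temperature":38.3}` or
`type":"cough"` with a base64-encoded WAV payload — with the server found
automatically from UDP announcements. A loopback mock server makes the full
path testable in-process.

## Worked example

```r
library(feverwatch)

# a drifting, noisy sensor: raw = 0.96*T + 0.8 + N(0, 0.1)
sen    <- sensor_model(gain = 0.96, offset = 0.8, noise_sd = 0.1, seed = 1)
frames <- simulate_warmup(thermal_scene(), sen, duration = 120)  # 2 min warm-up
warm   <- attr(frames, "scene")

regions <- detect_peltier_regions(frames, 33, 38)
fr      <- render_subject_frame(warm, validation_rig(38.2), sen, 121)
(reading <- measure_patient(fr, regions))
#> patient reading: 38.290 degC (raw 3x3 mean 37.578 at pixel [22,16])

id  <- make_device_id("ward3", "b8:27:eb:4f:12:9c")
pkt <- build_thermal_event(id, reading, time = 1700000121L)
packet_json(pkt)
#> {"id":"ward3-129C","time":1700000121,"type":"thermal","temperature":38.2901120308422}
```

The subject is held at 38.2 °C; despite the 4 % gain error, 0.8 °C offset
and pixel noise, the calibrated reading lands at 38.29 °C and — being
strictly above 38 °C — produces a thermal packet. A 25-measurement
validation campaign over 36.5–38.5 °C with the same sensor gives a mean
absolute error of 0.060 °C (max 0.139 °C):

```r
camp <- run_validation_campaign(c(36.5, 37, 37.5, 38, 38.5), sen, repetitions = 5)
mean(camp$error_C)   # 0.060
```

For the audio path:

```r
manifest <- build_dataset(2500, seed = 20)          # 500 clips/class, 70/20/10
fit <- train_model(build_model(model_config(seed = 7)), manifest, epochs = 4, seed = 7)
fit$accuracy                                        # 1.00 on the held-out test split
stream <- synth_stream(10, data.frame(label = "cough", time = 2.0), seed = 5)
classify_stream(stream, fit$model)
#>   start end label confidence
#> 1     2 3.5 cough  0.9999991
```

A command-line front end wraps the same functions
(`inst/cli/feverwatch help`): `simulate-thermal`, `calibrate`, `validate`,
`synth-audio`, `build-dataset`, `train`, `evaluate`, `detect`, `monitor`,
`serve-mock`, `discover`.

## Conventions

* Frames are R matrices (1-based, row 1 = top). The CSV export schema
  (`frames_to_csv()`: `frame_index,row,col,value`) uses 0-based row-major
  pixel indices.
* WAV I/O is 16-bit little-endian PCM with the canonical 44-byte header;
  sample k maps to amplitude k/32767 so generated clips round-trip
  bit-exactly.
* Packet JSON keys are lowercase and serialized in fixed order
  (`id`, `time`, `type`, payload); `time` is integer epoch seconds. The
  schema ships at `inst/schema/event-packet.schema.json`.

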