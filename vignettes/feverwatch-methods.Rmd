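---
title: "Methods: simulated non-contact fever and cough monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated non-contact fever and cough monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

feverwatch implements a complete contactless screening pipeline — thermal
self-calibration, cough classification, event telemetry — against bundled
simulators, so the whole system is reproducible and testable on a desk.
This vignette documents the models, the parameters that matter, the design
choices made where the design was genuinely open, and what the simulators
do and do not establish about real hardware.

## 1. The thermal measurement method

### Sensor and scene model

The imager is modelled at thermopile resolution, a 24×32 grid. Each raw
pixel reads

$$r = g\,T + b + \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2),$$

an affine error (gain $g$, offset $b$) plus i.i.d. Gaussian pixel noise.
This is exactly the error family a two-point calibration can cancel, which
is the point of the method: low-cost thermopiles drift in gain and offset
far more than they deviate from linearity inside a 5 °C span. Nonlinearity,
emissivity, distance attenuation and optical aberration are deliberately
out of model — the measurement protocol avoids the field-of-view extremes
rather than modelling them. Noise is a deterministic function of
`(seed, timestamp)`, so simulations are bit-reproducible.

The scene holds an ambient background (default 22 °C), two rectangular
Peltier reference patches (6×6 pixels, default setpoints 33 and 38 °C —
chosen to bracket the 36.5–38.5 °C screening range), and optionally a
hard-edged face disc constrained to 30–42 °C.

### Peltier plant and PID control

Each reference element is a first-order linear plant,

$$\frac{dT}{dt} = -k_\ell\,(T - T_\mathrm{amb}) + k_h\,d,$$

with heating rate $k_h = 0.5$ °C/s at full duty, loss rate
$k_\ell = 0.02$ s⁻¹, and duty cycle $d \in [0,1]$ set by a discrete PID
controller at $\Delta t = 0.5$ s. This is the simplest plant exhibiting the
observed warm-up behaviour (a capped initial ramp, exponential approach,
and a steady-state duty $d^* = k_\ell (T^* - T_\mathrm{amb})/k_h$). No
physical thermal constants are claimed; the values are stand-ins chosen
once for realistic time scales.

The PID gains are $k_p = 2$, $k_i = 0.2$, $k_d = 0.5$, integral clamp ±10,
with *conditional integration*: the integral does not accumulate while the
duty is saturated in the error's direction. Two tuning notes:

* Aggressive gains (e.g. $k_p = 8$, $k_d = 1$ at this $\Delta t$) put the
  proportional-plus-derivative gain at the Nyquist rate above the discrete
  stability bound of this plant and produce a sustained period-2 limit
  cycle of about ±0.11 °C with duty chattering against saturation. The
  chosen gains settle both setpoints within ≈60 s and hold them to well
  under ±0.1 °C indefinitely, so the two-minute warm-up budget is met with
  margin.
* Without conditional integration, the clamp alone permits an integral
  contribution of 5 full duty units after the long saturated ramp, causing
  degree-scale overshoot. Conditional integration is the standard remedy
  and keeps the stated clamp as a second line of defence.

Under constant duty the forward-Euler update has the exact closed form
$T_n = T_\infty + (T_0 - T_\infty)(1 - k_\ell \Delta t)^n$ with
$T_\infty = T_\mathrm{amb} + k_h d / k_\ell$; the test suite checks the
simulated trajectory against this discrete form to 10⁻⁶ °C at every step.
(The continuous-time exponential differs from the Euler trajectory at the
10⁻² °C level for this $\Delta t$; the discrete form is the correct
reference for the implemented update.)

### Reference self-detection

During warm-up only the references change temperature, so each pixel gets
a rise score: mean over the last $w$ frames minus mean over the first $w$
frames ($w = 5$ at 1 frame/s). Pixels scoring above half the smaller
reference rise (relative to the ambient estimate, the median of the early
mean frame) are grouped into 4-connected components; the two largest are
the references, the hotter (by final mean) is the high anchor, and the
exclusion mask is both regions dilated by 1 pixel — the margin keeps
bleed-over pixels from ever winning the patient argmax. Fewer than two
components is a hard "references not found" error; touching components are
an ambiguity error. With the default geometry the threshold sits roughly
5.5 °C above a noise floor of well under 0.1 °C, so detection recovers the
patch masks exactly in the noise-free case and with Jaccard ≥ 0.8 at
pixel noise of 0.2 °C.

### Calibration and patient measurement

The calibration anchors are the mean raw readings over each detected
region *in the current frame* — recalibration happens at every
measurement, so slow drift never accumulates. The straight line through
(r_lo, T_lo) and (r_hi, T_hi) is exact at both anchors by construction;
for a noise-free affine sensor it equals the inverse sensor map
(slope $1/g$, intercept $-b/g$), which is the parameter-recovery property
the acceptance tests check to 10⁻⁹ °C end to end. Degenerate anchors
(r_lo = r_hi) and inverted references (slope ≤ 0) are errors, not warnings.

The patient is the argmax over non-excluded pixels, ties broken by the
smallest row-major index (deterministic and testable); the reading is the
corrected mean of its 3×3 neighbourhood, intersected with the grid at
borders (a corner pixel averages its 4 in-grid cells). Reference
thermometer readings are modelled as plant truth plus a configurable bias
bounded at ±1 °C, matching the accuracy class of the I²C thermometers such
systems use.

### Validation-rig geometry

The validation tool is a temperature-controlled plate divided into nine
zones with bounded offsets from the plate mean. Two geometry choices are
worth recording:

* **The default plate fills the frame.** A hard-edged *interior* plate
  interacts badly with the deterministic tie-break: a uniform object's
  argmax lands on its top edge, where the 3×3 window mixes in ambient
  pixels and corrupts the reading by several degrees. Physically, the
  plate stands in for a patient's head at working distance and fills the
  view, with the reference elements in front of it. With that geometry
  every non-excluded pixel's neighbourhood is plate-valued, the noise-free
  campaign error is exactly zero, and the noisy campaign (σ = 0.2 °C,
  gain 0.97, offset 0.5, 25 measurements) stays at a mean absolute error
  of ≈0.06–0.1 °C — comfortably inside the 0.4 °C budget.
* **Zones tile by largest-remainder strips** (e.g. 24 rows split 8/8/8,
  32 columns split 11/11/10), so any block size carries exactly nine
  zones.

The same edge artifact is why the face disc is kept out of the calibration
and campaign paths: a uniform hard-edged disc has no interior-favouring
argmax under the mandated tie-break, blurred or not. Scripted monitor
scenarios therefore drive temperature through the rig geometry — which is
also how the integrated hardware test was run (cyclic temperature variation
produced by the validation tool while audio plays). This is a known
limitation of the hard-edge scene model, not of the measurement method.

### The bundled bench-validation table

`prototype_validation_table()` ships the recorded bench campaign of the
reference prototype: 25 rows of (measured, validation, |error|) over
36.5–38.5 °C, maximum error 0.9 °C, minimum 0.023 °C. The package verifies
the table row-wise (every error cell equals |measured − validation| within
print rounding) and by its extrema. A summary figure of 0.28 °C sometimes
quoted for this campaign is *not* recoverable as the arithmetic mean of the
printed error column (which is 0.377 °C); since the computation behind that
summary is unstated, the row-wise and extremum checks stand in for it.

## 2. The audio front end

Clips are standardized to mono (channel mean), resampled to 16 kHz
(polyphase), right-trimmed or zero-padded to 1 s (16,000 samples) or 2 s
(32,000), and clamped to [−1, 1]. A conforming clip passes through
bit-for-bit.

**The silence gate runs on raw amplitude, before any normalization.** The
gate is `RMS < 0.01` of full scale (strict, so a clip exactly at threshold
is processed). Gating after peak normalization is a real failure mode —
normalization rescales a quiet clip to full amplitude and the gate never
fires — and the suite keeps a regression test for exactly that ordering.

The spectrogram uses a 256-point FFT with a 256-sample periodic Hann
window, hop 100 samples, and end-padding so the frame count is
⌈N/hop⌉: 129 frequency bins at 62.5 Hz spacing and 160 frames per 1 s
clip. This is the unique simple parameterization producing the (129, 160)
input shape at 16 kHz; descriptions of such front ends in terms of
"≈30 ms windows" refer to UI-level framing and cannot yield 129 bins, so
the FFT-length convention is used throughout. The same front end applied
to 2 s clips yields (129, 320); no alternative shape is special-cased for
longer clips, keeping one consistent transform.

Two fixed stages then produce the model input: a bilinear resize of the
time axis from 160 to 124 columns (half-pixel centers, corner alignment
off — ordinary image-resize semantics), and per-sample standardization
$(x - \mu)/\max(\sigma, 10^{-6})$ over all pixels of the sample. The ε
floor maps constant spectrograms to all-zero inputs instead of dividing by
zero. Statistics are per sample, not per corpus: no training-set statistics
are baked into the preprocessing, so inference needs no side data.

## 3. Synthetic audio classes

The generator produces five classes, deterministic per `(label, seed)`,
quantized to the 16-bit grid so WAV files round-trip exactly:

* **cough** — one or two exponentially decaying broadband bursts
  (80–300 ms), band-emphasized 300–3000 Hz, peak 0.6–0.95;
* **other** — transients and tones violating the cough envelope: click
  trains, steady tones (200–6000 Hz), chirps;
* **music** — 4–8 pentatonic notes with up to three harmonics and smooth
  onsets;
* **conversation** — band-limited noise through one of two formant presets
  (lower/higher voice, an approximately even mix), amplitude-modulated at
  3–6 Hz (syllabic rate);
* **ambient** — low-level 1/f noise, loud enough (RMS ≈ 0.03–0.05) that it
  is classified as ambient rather than silence-gated away.

Realism is a non-goal. The classes are designed to be *statistically*
separable the way the real corpus classes were: a deliberately simple
nearest-centroid classifier on three analytic features (300–3000 Hz
band-energy ratio, envelope kurtosis, log RMS) reaches ≈90 % held-out
accuracy, which (a) proves the classes are learnable so the CNN acceptance
test is not vacuous, and (b) provides the yardstick the CNN must beat.
What passing tests on this data establishes is that the *pipeline* —
preprocessing, training loop, evaluation bookkeeping, streaming logic — is
correct; they say nothing about accuracy on real coughs, which depends on
data this package intentionally does not contain.

`build_dataset()` allocates clips per class (balanced, largest-remainder
when not divisible) and splits each class 70/20/10 into train/validation/
test by seeded shuffle with largest-remainder counts; 5000 clips give
exactly 1000 per class and 3500/1000/500 overall. Manifests record each
clip's seed, so clips resolve identically from WAV files or by
re-synthesis.

## 4. The classifier

A small convolutional network over the 129×124 standardized spectrogram:
3×3 convolution with 16 filters, ReLU, 2×2 max-pool; 3×3 convolution with
32 filters, ReLU, 2×2 max-pool; dropout 0.25 on the flattened features;
dense 64 with ReLU; softmax over K ∈ {2, 5} classes (default 5). The exact
stack is fixed in `model_config()` for reproducibility; initialization is
He-normal under the config seed (Glorot-scaled at the softmax so initial
logits stay moderate), and training is seeded Adam (lr 10⁻³, batch 32,
4 epochs by default) on softmax cross-entropy, implemented in compiled
code as im2col + GEMM. Shuffling and dropout derive from the training
seed, so runs are exactly repeatable.

Desk-scale study conditions: 500 clips per class (2500 total), 4 epochs —
about two minutes of training on one CPU core. Under those conditions the
held-out accuracy criterion is ≥ 90 % and the model must beat the analytic
baseline; in practice it reaches ≈100 % on the synthetic classes.
Confusion matrices are kept as exact counts (rows = true class), with
accuracy defined as trace over sum — identities the tests assert exactly.

**Streaming.** Windows of 1 s slide at 0.5 s hop (50 % overlap);
silence-gated windows are skipped; consecutive cough windows merge into
one event, with a new event only after a gap above 0.5 s. The overlap is
the remedy for the boundary-splitting failure (a cough falling across two
windows and detected in neither); the debounce prevents one cough pair in
quick succession from registering as many events while keeping bursts 3 s
apart distinct.

## 5. Telemetry conventions

Where the transport design was open, one convention is fixed and
documented:

* JSON keys are all lowercase — `id`, `time`, `type`, `temperature`,
  `audio` — serialized in that fixed order (a golden-file test pins the
  byte layout); `time` is integer epoch seconds (no sub-second precision
  is claimed anywhere in the system).
* The device id is `common_name + "-" + last four hex digits of the MAC`,
  uppercase, independent of separator style.
* Thermal packets are emitted only strictly above 38.0 °C; the monitor
  adds hysteresis (re-arm 0.2 °C below threshold) so one febrile episode
  produces one packet rather than a packet per frame.
* Cough packets embed the clip's complete WAV bytes as base64 (44-byte
  canonical header + PCM; 42,728 base64 characters for a 1 s clip), capped
  at 256 KiB per packet.
* Transport is newline-delimited UTF-8 JSON over TCP, the simplest
  interoperable framing; the mock server acknowledges each packet by
  echoing its id. Discovery listens for UDP announcements
  `{"service":"feverwatch","ip":...,"port":...}` (default port 5005);
  the first valid announcement wins, malformed datagrams are ignored,
  repeated announcements only refresh the endpoint. Transport failures
  raise classed, retriable conditions rather than crashing the monitor;
  with no server discovered the monitor runs offline and keeps every event
  in its local log.

## 6. Numerical choices and degenerate inputs

* Calibration anchors are exact by construction (tested to 10⁻¹² °C);
  degenerate and inverted anchors are errors.
* Amplitudes map to the 16-bit grid as k/32767, making quantization
  idempotent and WAV round trips exact.
* The standardization ε is 10⁻⁶; constant inputs map to zero.
* Zero-duration warm-ups, empty audio, all-NaN audio, streams shorter than
  one window, all-excluded frames, and single-class training manifests are
  all explicit errors or warnings, not silent degradation.
* All randomness (sensor noise, clip synthesis, split assignment, weight
  init, shuffling, dropout) flows from user-visible integer seeds below
  2³¹; equal seeds give bit-identical frames, waveforms, manifests and
  trained weights.

## 7. Test problem sizes

The suite exercises the study conditions at desk scale: 120 s warm-ups at
1 frame/s; 25-measurement validation campaigns; a shared 400-clip dataset
(80 per class) for classifier and streaming behaviour tests; the full
2500-clip, 4-epoch training run in the acceptance tests; and loopback
interoperability with 100 packets. Everything runs in minutes on one CPU.

## 8. Known limitations

* The thermal model is affine-plus-noise; real thermopiles add
  fixed-pattern noise, temperature-dependent gain and optics effects the
  calibration may only partially cancel.
* Hard-edged scene objects make argmax behaviour at object boundaries
  artificial (see the rig-geometry discussion); real faces have smooth
  thermal profiles whose maximum is interior.
* Synthetic audio proves pipeline correctness, not clinical performance;
  no claim about real-cough accuracy is made or testable here.
* The transport layer is deliberately plain TCP/UDP JSON on a trusted
  network; authentication and encryption are out of scope.
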