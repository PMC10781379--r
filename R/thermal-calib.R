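# Self-calibrating temperature measurement: detect the two Peltier reference
# regions from warm-up fluctuations, fit the per-measurement two-point
# calibration line, locate the patient as the hottest non-reference pixel,
# and correct the 3x3 neighbourhood mean through the line.

# 4-connected component labelling on a logical matrix (BFS; deterministic,
# labels assigned in row-major scan order of the component seeds).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nlab <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (mask[r0, c0] && lab[r0, c0] == 0L) {
        nlab <- nlab + 1L
        queue <- matrix(c(r0, c0), ncol = 2)
        lab[r0, c0] <- nlab
        while (nrow(queue) > 0) {
          r <- queue[1, 1]; cc <- queue[1, 2]
          queue <- queue[-1, , drop = FALSE]
          for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
            rr <- r + d[1]; ccc <- cc + d[2]
            if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= nc &&
                mask[rr, ccc] && lab[rr, ccc] == 0L) {
              lab[rr, ccc] <- nlab
              queue <- rbind(queue, c(rr, ccc))
            }
          }
        }
      }
    }
  }
  lab
}

# Dilate a logical mask by `margin` pixels (Chebyshev / 8-neighbourhood).
dilate_mask <- function(mask, margin = 1L) {
  if (margin < 1) return(mask)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    rows <- max(1, idx[k, 1] - margin):min(nr, idx[k, 1] + margin)
    cols <- max(1, idx[k, 2] - margin):min(nc, idx[k, 2] + margin)
    out[rows, cols] <- TRUE
  }
  out
}

#' Self-detect the Peltier reference regions from warm-up frames
#'
#' During warm-up only the Peltier references change temperature, so a
#' per-pixel rise score — mean over the last `window` frames minus mean over
#' the first `window` frames — isolates them. Pixels whose score exceeds the
#' threshold (half the smaller reference rise above the estimated ambient,
#' by default) are grouped into 4-connected components; the two largest
#' become the reference regions, the hotter one (by final-window mean) is
#' assigned the high reference, and the exclusion mask is both regions
#' dilated by `margin` pixels.
#'
#' @param warmup_frames List of at least 10 `thermal_frame`s spanning warm-up.
#' @param ref_low,ref_high Reference thermometer readings (degC),
#'   `ref_low < ref_high`.
#' @param window Frames in each averaging window.
#' @param threshold Rise-score threshold (degC); default
#'   `(ref_low - ambient_estimate) / 2` with ambient estimated as the median
#'   of the early-window mean frame.
#' @param margin Exclusion-mask dilation (pixels).
#' @return An object of class `peltier_regions`: logical matrices
#'   `low_pixels`, `high_pixels`, `exclusion_mask`, plus `ref_low`,
#'   `ref_high`.
#' @export
detect_peltier_regions <- function(warmup_frames, ref_low, ref_high,
                                   window = 5L, threshold = NULL,
                                   margin = 1L) {
  if (length(warmup_frames) < 10) {
    stopf("need at least 10 warm-up frames, got %d", length(warmup_frames))
  }
  if (!(ref_low < ref_high)) stopf("ref_low must be below ref_high")
  early <- Reduce(`+`, warmup_frames[seq_len(window)]) / window
  n <- length(warmup_frames)
  late <- Reduce(`+`, warmup_frames[(n - window + 1L):n]) / window
  score <- late - early
  if (is.null(threshold)) {
    ambient_est <- stats::median(early)
    threshold <- (ref_low - ambient_est) / 2
    if (threshold <= 0) stopf("reference temperatures are not above ambient")
  }
  lab <- label_components(score > threshold)
  if (max(lab) < 2) {
    stopf("references not found: fewer than two rising regions (got %d)",
          max(lab))
  }
  sizes <- tabulate(lab[lab > 0])
  top2 <- order(sizes, decreasing = TRUE)[1:2]
  m1 <- lab == top2[1]
  m2 <- lab == top2[2]
  if (any(dilate_mask(m1, 1L) & m2)) {
    stopf("ambiguous references: the two rising regions touch")
  }
  mean1 <- mean(late[m1]); mean2 <- mean(late[m2])
  if (mean1 >= mean2) {
    high <- m1; low <- m2
  } else {
    high <- m2; low <- m1
  }
  structure(
    list(low_pixels = low, high_pixels = high,
         exclusion_mask = dilate_mask(low | high, margin),
         ref_low = ref_low, ref_high = ref_high),
    class = "peltier_regions"
  )
}

#' Fit the two-point calibration line
#'
#' The affine raw-to-corrected map anchored at the two reference readings:
#' `slope = (ref_high - ref_low) / (raw_high - raw_low)`, intercept such that
#' the curve is exact at both anchors. A sensor with error
#' `raw = gain * true + offset` yields the inverse map
#' `slope = 1/gain`, `intercept = -offset/gain`.
#'
#' @param raw_low,raw_high Thermopile readings over the two references (degC).
#' @param ref_low,ref_high Reference thermometer temperatures (degC).
#' @return An object of class `calibration_curve` with `slope`, `intercept`.
#' @export
#' @examples
#' cc <- fit_calibration(31, 33, 36, 38)
#' cc$slope; cc$intercept
fit_calibration <- function(raw_low, ref_low, raw_high, ref_high) {
  if (raw_high == raw_low) {
    stopf("degenerate calibration: identical raw readings at both references")
  }
  slope <- (ref_high - ref_low) / (raw_high - raw_low)
  if (!is.finite(slope) || slope <= 0) {
    stopf("inverted references: calibration slope must be positive")
  }
  structure(list(slope = slope, intercept = ref_low - slope * raw_low),
            class = "calibration_curve")
}

#' Apply a calibration curve
#'
#' @param curve A [fit_calibration()] result.
#' @param raw Raw reading(s) (degC).
#' @return Corrected temperature(s): `slope * raw + intercept`.
#' @export
apply_calibration <- function(curve, raw) curve$slope * raw + curve$intercept

#' Locate the patient pixel
#'
#' The hottest pixel outside the exclusion mask; ties broken by the smallest
#' row-major index (top row first, then left to right).
#'
#' @param frame A `thermal_frame` (numeric matrix).
#' @param exclusion_mask Logical matrix of pixels to ignore (the dilated
#'   reference regions), or `NULL`.
#' @return `c(row, col)` (1-based).
#' @export
locate_patient <- function(frame, exclusion_mask = NULL) {
  vals <- unclass(frame)
  if (!is.null(exclusion_mask)) vals[exclusion_mask] <- -Inf
  if (all(!is.finite(vals))) stopf("all pixels are excluded")
  best <- max(vals)
  hits <- which(vals == best, arr.ind = TRUE)
  # row-major tie-break: smallest row, then smallest column
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  c(row = unname(hits[1, 1]), col = unname(hits[1, 2]))
}

#' Measure the patient temperature
#'
#' Averages the raw reading over the 3x3 neighbourhood of the patient pixel
#' (intersected with the grid at borders, so corner pixels average 4 cells)
#' and corrects it through the calibration curve.
#'
#' @param frame A `thermal_frame`.
#' @param pixel `c(row, col)` from [locate_patient()].
#' @param curve A `calibration_curve`.
#' @return An object of class `patient_reading`: `pixel`, `raw_mean`,
#'   `corrected`, `timestamp`.
#' @export
patient_temperature <- function(frame, pixel, curve) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (pixel[1] < 1 || pixel[1] > nr || pixel[2] < 1 || pixel[2] > nc) {
    stopf("pixel (%d,%d) outside the %dx%d grid", pixel[1], pixel[2], nr, nc)
  }
  rows <- max(1, pixel[1] - 1):min(nr, pixel[1] + 1)
  cols <- max(1, pixel[2] - 1):min(nc, pixel[2] + 1)
  raw_mean <- mean(unclass(frame)[rows, cols])
  structure(
    list(pixel = pixel, raw_mean = raw_mean,
         corrected = apply_calibration(curve, raw_mean),
         timestamp = attr(frame, "timestamp") %||% NA_real_),
    class = "patient_reading"
  )
}

#' @export
print.patient_reading <- function(x, ...) {
  cat(sprintf("patient reading: %.3f degC (raw 3x3 mean %.3f at pixel [%d,%d])\n",
              x$corrected, x$raw_mean, x$pixel[1], x$pixel[2]))
  invisible(x)
}

# Reference thermometer readings for a scene: plant truth plus a bounded bias
# (the reference thermometers are rated to +/- 1 degC).
reference_readings <- function(scene, ref_bias = c(0, 0)) {
  if (any(abs(ref_bias) > 1)) stopf("reference thermometer bias exceeds 1 degC")
  temps <- vapply(scene$peltier_patches, function(p) p$plant$temp, numeric(1))
  ord <- order(temps)
  c(low = temps[ord[1]] + ref_bias[1], high = temps[ord[2]] + ref_bias[2])
}

# Anchor raw values: mean raw reading over each detected region in `frame`.
calibration_from_frame <- function(frame, regions) {
  raw_low <- mean(unclass(frame)[regions$low_pixels])
  raw_high <- mean(unclass(frame)[regions$high_pixels])
  fit_calibration(raw_low, regions$ref_low, raw_high, regions$ref_high)
}

#' Full single measurement: calibrate, locate, correct
#'
#' Per-measurement recalibration: the calibration anchors are the region
#' means in the *current* frame, so slow sensor drift is corrected at every
#' measurement.
#'
#' @param frame A `thermal_frame` containing references and subject.
#' @param regions A `peltier_regions` from [detect_peltier_regions()].
#' @return A `patient_reading`.
#' @export
measure_patient <- function(frame, regions) {
  curve <- calibration_from_frame(frame, regions)
  pixel <- locate_patient(frame, regions$exclusion_mask)
  patient_temperature(frame, pixel, curve)
}

#' Run a validation campaign against the heated-plate rig
#'
#' For each validation temperature (and repetition): simulate the warm-up,
#' self-detect the references and calibrate, place the nine-zone validation
#' plate in the scene, measure it as a patient, and record
#' `(measured, validation, |error|)`.
#'
#' @param validation_temps Plate temperatures to test (degC, within
#'   \[30, 42\]).
#' @param sensor A [sensor_model()].
#' @param repetitions Measurements per temperature.
#' @param scene Calibration scene (references only; default layout).
#' @param zone_offsets Per-zone plate non-uniformity (degC, length 9).
#' @param warmup_duration Warm-up length (s).
#' @param ref_bias Length-2 reference thermometer bias (degC, within +/- 1).
#' @param csv Optional path; if given, the records are also written as CSV
#'   with header `measured_C,validation_C,error_C`.
#' @return Data frame with columns `measured_C`, `validation_C`, `error_C`.
#' @export
run_validation_campaign <- function(validation_temps, sensor,
                                    repetitions = 1,
                                    scene = thermal_scene(),
                                    zone_offsets = rep(0, 9),
                                    warmup_duration = 120,
                                    ref_bias = c(0, 0),
                                    csv = NULL) {
  if (any(validation_temps < 30 | validation_temps > 42)) {
    stopf("validation temperatures must lie within [30, 42] degC")
  }
  records <- list()
  k <- 0L
  for (rep_i in seq_len(repetitions)) {
    # one warm-up + detection per repetition; noise differs per repetition
    # through the frame timestamps
    sensor_rep <- sensor
    sensor_rep$seed <- mix_seed(sensor$seed, rep_i)
    frames <- simulate_warmup(scene, sensor_rep, duration = warmup_duration)
    warm_scene <- attr(frames, "scene")
    refs <- reference_readings(warm_scene, ref_bias)
    regions <- detect_peltier_regions(frames, refs["low"], refs["high"])
    for (vt in validation_temps) {
      k <- k + 1L
      rig <- validation_rig(vt, zone_offsets)
      frame <- render_subject_frame(warm_scene, rig, sensor_rep,
                                    timestamp = warmup_duration + k)
      reading <- measure_patient(frame, regions)
      records[[k]] <- data.frame(
        measured_C = reading$corrected,
        validation_C = vt,
        error_C = abs(reading$corrected - vt)
      )
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}

#' Bench validation measurements of the reference prototype
#'
#' The recorded bench campaign of the hardware prototype this package
#' simulates: thermopile-measured versus reference-plate temperatures over
#' the 36.5-38.5 degC screening range, 25 measurements. Used to verify the
#' error bookkeeping (`error = |measured - validation|`) row by row.
#'
#' @return Data frame with columns `measured_C`, `validation_C`, `error_C`.
#' @export
#' @examples
#' tbl <- prototype_validation_table()
#' max(tbl$error_C)
prototype_validation_table <- function() {
  path <- system.file("extdata", "prototype_validation.csv",
                      package = "feverwatch", mustWork = TRUE)
  utils::read.csv(path)
}
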