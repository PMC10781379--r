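# Synthetic thermopile scene simulator: PID-heated Peltier reference patches,
# a face blob, an affine-plus-noise sensor model, and the 9-zone validation
# plate rig. Everything downstream (self-detection, calibration, validation
# campaigns) runs against these frames, so no hardware is needed.

#' First-order Peltier plant
#'
#' Models a Peltier reference element as a first-order linear heater:
#' `dT/dt = -k_loss * (T - ambient) + k_heat * duty`. With constant duty `d`
#' the analytic steady state is `ambient + k_heat * d / k_loss`.
#'
#' @param setpoint Target temperature (degC).
#' @param temp Initial element temperature (degC); defaults to `ambient`.
#' @param k_heat Heating rate at full duty (degC/s). Must be > 0.
#' @param k_loss Passive loss rate (1/s). Must be > 0.
#' @param ambient Ambient temperature (degC).
#' @return An object of class `peltier_plant`.
#' @export
#' @examples
#' p <- peltier_plant(setpoint = 38)
#' p$temp
peltier_plant <- function(setpoint, temp = ambient, k_heat = 0.5,
                          k_loss = 0.02, ambient = 22) {
  if (!is_scalar_num(k_heat) || k_heat <= 0) stopf("k_heat must be > 0")
  if (!is_scalar_num(k_loss) || k_loss <= 0) stopf("k_loss must be > 0")
  if (!is_scalar_num(setpoint)) stopf("setpoint must be a finite number")
  structure(
    list(temp = temp, setpoint = setpoint, k_heat = k_heat,
         k_loss = k_loss, ambient = ambient),
    class = "peltier_plant"
  )
}

#' Discrete PID controller state
#'
#' Proportional-integral-derivative state used to drive a Peltier plant's PWM
#' duty cycle toward its setpoint. The duty cycle is clamped to \[0, 1\] and
#' the integral is clamped to `+/- integral_clamp`; additionally the integral
#' does not accumulate while the duty is saturated in the direction of the
#' error (conditional integration), which prevents windup overshoot during
#' the long full-power warm-up ramp.
#'
#' @param kp,ki,kd PID gains.
#' @param dt Controller step (s).
#' @param integral_clamp Anti-windup bound on the accumulated error.
#' @return An object of class `pid_state`.
#' @export
pid_state <- function(kp = 2, ki = 0.2, kd = 0.5, dt = 0.5,
                      integral_clamp = 10) {
  gains <- c(kp, ki, kd)
  if (any(!is.finite(gains))) stopf("PID gains must be finite")
  if (!is_scalar_num(dt) || dt <= 0) stopf("dt must be > 0")
  structure(
    list(kp = kp, ki = ki, kd = kd, dt = dt,
         integral = 0, prev_error = 0, duty = 0,
         integral_clamp = integral_clamp),
    class = "pid_state"
  )
}

#' Advance a Peltier plant one open-loop step
#'
#' Forward-Euler update of the first-order plant under a fixed duty cycle.
#' The discrete trajectory under constant duty has the exact closed form
#' `T_n = T_inf + (T_0 - T_inf) * (1 - k_loss * dt)^n` with
#' `T_inf = ambient + k_heat * duty / k_loss`.
#'
#' @param plant A [peltier_plant()].
#' @param duty Duty cycle in \[0, 1\].
#' @param dt Time step (s).
#' @return The advanced plant.
#' @export
step_plant <- function(plant, duty, dt) {
  duty <- clamp(duty, 0, 1)
  dT <- (-plant$k_loss * (plant$temp - plant$ambient) + plant$k_heat * duty) * dt
  plant$temp <- plant$temp + dT
  plant
}

#' One closed-loop PID step
#'
#' Computes the PID duty for the current error, advances the plant by one
#' step of `pid$dt`, and returns the updated triple.
#'
#' @param plant A [peltier_plant()].
#' @param pid A [pid_state()].
#' @param setpoint Target temperature; defaults to the plant's own setpoint.
#' @return `list(duty, plant, pid)`.
#' @export
step_pid <- function(plant, pid, setpoint = plant$setpoint) {
  err <- setpoint - plant$temp
  deriv <- (err - pid$prev_error) / pid$dt
  # candidate integral, then clamp (anti-windup bound)
  new_int <- clamp(pid$integral + err * pid$dt,
                   -pid$integral_clamp, pid$integral_clamp)
  u <- pid$kp * err + pid$ki * new_int + pid$kd * deriv
  duty <- clamp(u, 0, 1)
  # conditional integration: discard the accumulation when the actuator is
  # saturated in the error's direction (it cannot act on the extra error)
  saturated <- (u > 1 && err > 0) || (u < 0 && err < 0)
  if (!saturated) pid$integral <- new_int
  pid$prev_error <- err
  pid$duty <- duty
  plant <- step_plant(plant, duty, pid$dt)
  list(duty = duty, plant = plant, pid = pid)
}

#' Simulate a PID-controlled Peltier warm-up trajectory
#'
#' Runs the closed loop from the plant's initial temperature for `duration`
#' simulated seconds and returns the temperature/duty trajectory. This is the
#' plant-level view of the warm-up that [simulate_warmup()] renders as frames.
#'
#' @param plant A [peltier_plant()].
#' @param pid A [pid_state()].
#' @param duration Simulated time (s).
#' @return A data frame with columns `time`, `temp`, `duty` (one row per
#'   controller step; `time` is the time after the step).
#' @export
#' @examples
#' tr <- simulate_plant(peltier_plant(33), pid_state(), duration = 300)
#' mean(tr$temp[tr$time > 270])
simulate_plant <- function(plant, pid = pid_state(), duration = 300) {
  n <- floor(duration / pid$dt)
  if (n < 1) stopf("duration must cover at least one PID step")
  out <- data.frame(time = numeric(n), temp = numeric(n), duty = numeric(n))
  for (i in seq_len(n)) {
    st <- step_pid(plant, pid)
    plant <- st$plant
    pid <- st$pid
    out$time[i] <- i * pid$dt
    out$temp[i] <- plant$temp
    out$duty[i] <- st$duty
  }
  out
}

#' Rectangular Peltier reference patch in the scene
#'
#' @param origin `(row, col)` of the patch's top-left pixel (1-based).
#' @param height,width Patch extent in pixels.
#' @param plant The [peltier_plant()] heating this patch.
#' @return An object of class `peltier_patch`.
#' @export
peltier_patch <- function(origin, height, width, plant) {
  structure(list(origin = as.integer(origin), height = as.integer(height),
                 width = as.integer(width), plant = plant),
            class = "peltier_patch")
}

patch_rows <- function(p) seq(p$origin[1], p$origin[1] + p$height - 1L)
patch_cols <- function(p) seq(p$origin[2], p$origin[2] + p$width - 1L)

#' Thermal scene viewed by the thermopile
#'
#' A 24x32 (by default) scene holding the ambient background, an optional
#' face disc, and the two Peltier reference patches. Patch placement is
#' validated: patches must lie fully inside the grid and must not overlap.
#'
#' @param grid_rows,grid_cols Sensor resolution (rows x cols).
#' @param ambient Background temperature (degC).
#' @param face `NULL` or `list(center = c(row, col), radius, temp)`; the face
#'   is a hard-edged disc at `temp` (30-42 degC).
#' @param peltier_patches List of [peltier_patch()] objects.
#' @param fov_deg Informational field of view (degrees).
#' @return An object of class `thermal_scene`.
#' @export
#' @examples
#' sc <- thermal_scene(face = list(center = c(17, 17), radius = 5, temp = 37))
thermal_scene <- function(grid_rows = 24, grid_cols = 32, ambient = 22,
                          face = NULL,
                          peltier_patches = default_peltier_patches(ambient),
                          fov_deg = c(110, 75)) {
  sc <- structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         ambient = ambient, face = face, peltier_patches = peltier_patches,
         fov_deg = fov_deg),
    class = "thermal_scene"
  )
  validate_scene(sc)
  sc
}

#' Default reference patch layout
#'
#' Two 6x6 patches near the top corners of the grid, one regulated to 33 degC
#' and one to 38 degC (the low/high calibration references).
#'
#' @param ambient Ambient temperature the plants start from (degC).
#' @param setpoints Length-2 numeric, low and high reference setpoints (degC).
#' @return List of two [peltier_patch()] objects.
#' @export
default_peltier_patches <- function(ambient = 22, setpoints = c(33, 38)) {
  list(
    peltier_patch(c(5L, 4L), 6L, 6L,
                  peltier_plant(setpoints[1], ambient = ambient)),
    peltier_patch(c(5L, 24L), 6L, 6L,
                  peltier_plant(setpoints[2], ambient = ambient))
  )
}

validate_scene <- function(sc) {
  for (p in sc$peltier_patches) {
    r <- patch_rows(p); co <- patch_cols(p)
    if (min(r) < 1 || max(r) > sc$grid_rows ||
        min(co) < 1 || max(co) > sc$grid_cols) {
      stopf("peltier patch at (%d,%d) extends outside the %dx%d grid",
            p$origin[1], p$origin[2], sc$grid_rows, sc$grid_cols)
    }
  }
  if (length(sc$peltier_patches) == 2) {
    p1 <- sc$peltier_patches[[1]]; p2 <- sc$peltier_patches[[2]]
    overlap <- length(intersect(patch_rows(p1), patch_rows(p2))) > 0 &&
      length(intersect(patch_cols(p1), patch_cols(p2))) > 0
    if (overlap) stopf("peltier patches overlap")
  }
  if (!is.null(sc$face)) {
    if (sc$face$temp < 30 || sc$face$temp > 42) {
      stopf("face temperature must lie in [30, 42] degC")
    }
  }
  invisible(sc)
}

#' Affine-plus-noise thermopile sensor model
#'
#' Models the raw thermopile error the two-point calibration corrects:
#' `raw = gain * true + offset + noise`, with i.i.d. Gaussian pixel noise.
#' The noise realization is a deterministic function of `(seed, timestamp)`,
#' so identical simulations are bit-identical.
#'
#' @param gain Multiplicative error (> 0), dimensionless.
#' @param offset Additive error (degC).
#' @param noise_sd Pixel noise standard deviation (degC, >= 0).
#' @param seed Integer noise seed.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(gain = 1, offset = 0, noise_sd = 0, seed = 1L) {
  if (!is_scalar_num(gain) || gain <= 0) stopf("gain must be > 0")
  if (!is_scalar_num(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(gain = gain, offset = offset, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sensor_model")
}

# Ground-truth temperature grid of a scene (face drawn first, patches on top).
scene_truth <- function(scene) {
  g <- matrix(scene$ambient, scene$grid_rows, scene$grid_cols)
  if (!is.null(scene$face)) {
    f <- scene$face
    rows <- matrix(seq_len(scene$grid_rows), scene$grid_rows, scene$grid_cols)
    cols <- matrix(seq_len(scene$grid_cols), scene$grid_rows, scene$grid_cols,
                   byrow = TRUE)
    disc <- (rows - f$center[1])^2 + (cols - f$center[2])^2 <= f$radius^2
    g[disc] <- f$temp
  }
  for (p in scene$peltier_patches) {
    g[patch_rows(p), patch_cols(p)] <- p$plant$temp
  }
  g
}

apply_sensor <- function(truth, sensor, timestamp) {
  raw <- sensor$gain * truth + sensor$offset
  if (sensor$noise_sd > 0) {
    noise <- with_local_seed(
      mix_seed(sensor$seed, round(timestamp * 1000)),
      matrix(stats::rnorm(length(truth), 0, sensor$noise_sd),
             nrow(truth), ncol(truth))
    )
    raw <- raw + noise
  }
  raw
}

new_thermal_frame <- function(values, timestamp) {
  structure(values, timestamp = timestamp,
            class = c("thermal_frame", class(values)))
}

#' Render one raw thermopile frame
#'
#' Applies the sensor model to the scene's ground-truth temperature grid:
#' ambient outside objects, plant temperature inside reference patches, face
#' temperature inside the face disc.
#'
#' @param scene A [thermal_scene()].
#' @param sensor A [sensor_model()].
#' @param timestamp Frame time (s); also indexes the noise realization.
#' @return A `thermal_frame`: `grid_rows x grid_cols` numeric matrix with a
#'   `timestamp` attribute.
#' @export
#' @examples
#' fr <- render_frame(thermal_scene(), sensor_model(), timestamp = 0)
#' dim(fr)
render_frame <- function(scene, sensor, timestamp = 0) {
  validate_scene(scene)
  new_thermal_frame(apply_sensor(scene_truth(scene), sensor, timestamp),
                    timestamp)
}

#' Simulate the calibration warm-up as a frame sequence
#'
#' Starts the Peltier plants at their initial (room) temperature, runs both
#' PID loops toward their setpoints, and renders a frame every
#' `frame_period` seconds. The scene is otherwise static: during warm-up no
#' other thermal object may move, because reference self-detection relies on
#' the references being the only pixels whose temperature changes.
#'
#' @param scene A [thermal_scene()].
#' @param sensor A [sensor_model()].
#' @param duration Warm-up length (s); must cover at least one frame.
#' @param frame_period Seconds between rendered frames.
#' @param pid Prototype [pid_state()] used for both plants.
#' @return List of `thermal_frame`s (chronological), with the final scene
#'   (plants at their end-of-warm-up temperatures) in attribute `scene`.
#' @export
simulate_warmup <- function(scene, sensor, duration = 120, frame_period = 1,
                            pid = pid_state()) {
  if (!is_scalar_num(duration) || duration < frame_period) {
    stopf("duration must be at least one frame_period")
  }
  steps_per_frame <- frame_period / pid$dt
  if (abs(steps_per_frame - round(steps_per_frame)) > 1e-9) {
    stopf("frame_period must be a multiple of the PID dt")
  }
  steps_per_frame <- as.integer(round(steps_per_frame))
  n_frames <- as.integer(floor(duration / frame_period))
  pids <- lapply(scene$peltier_patches, function(p) pid)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    for (s in seq_len(steps_per_frame)) {
      for (j in seq_along(scene$peltier_patches)) {
        st <- step_pid(scene$peltier_patches[[j]]$plant, pids[[j]])
        scene$peltier_patches[[j]]$plant <- st$plant
        pids[[j]] <- st$pid
      }
    }
    frames[[k]] <- render_frame(scene, sensor, timestamp = k * frame_period)
  }
  attr(frames, "scene") <- scene
  frames
}

#' Validation rig: heated plate divided into nine zones
#'
#' Models the validation tool: an aluminium plate held at `plate_temp`,
#' covering a rectangular pixel block on the imager, and divided into a 3x3
#' grid of zones whose temperatures deviate from the plate mean by
#' `zone_offsets` (checked against `uniformity_bound`).
#'
#' @param plate_temp Plate temperature (degC).
#' @param zone_offsets Nine per-zone offsets (degC), zone order row-major.
#' @param plate_block `c(row, col, height, width)` pixel rectangle (1-based
#'   origin) the plate covers. The default covers the whole frame: in the
#'   validation protocol the plate stands in for the patient's head and
#'   fills the field of view (the references are rendered in front of it).
#' @param uniformity_bound Maximum allowed `|zone_offset|` (degC).
#' @return An object of class `validation_rig`.
#' @export
validation_rig <- function(plate_temp, zone_offsets = rep(0, 9),
                           plate_block = c(1L, 1L, 24L, 32L),
                           uniformity_bound = 0.5) {
  if (length(zone_offsets) != 9) stopf("zone_offsets must have length 9")
  if (any(abs(zone_offsets) > uniformity_bound)) {
    stopf("zone offsets exceed the uniformity bound (%.2f degC)",
          uniformity_bound)
  }
  if (plate_block[3] < 3 || plate_block[4] < 3) {
    stopf("plate block must be at least 3x3 pixels (nine zones)")
  }
  structure(list(plate_temp = plate_temp, zone_offsets = zone_offsets,
                 plate_block = as.integer(plate_block)),
            class = "validation_rig")
}

# 3x3 zone tiling of the plate block: near-equal strips (largest remainder),
# so the nine zones exactly tile any block size.
zone_strips <- function(extent) {
  sizes <- allocate_largest_remainder(extent, rep(1, 3))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  cbind(start = starts, end = ends)
}

# True temperature grid contribution of the rig (overlays `truth` in place).
overlay_rig <- function(truth, rig) {
  b <- rig$plate_block
  if (b[1] < 1 || b[2] < 1 || b[1] + b[3] - 1 > nrow(truth) ||
      b[2] + b[4] - 1 > ncol(truth)) {
    stopf("validation plate block extends outside the grid")
  }
  rs <- zone_strips(b[3])
  cs <- zone_strips(b[4])
  for (zr in 1:3) {
    for (zc in 1:3) {
      zone <- (zr - 1L) * 3L + zc
      rows <- (b[1] + rs[zr, "start"] - 1L):(b[1] + rs[zr, "end"] - 1L)
      cols <- (b[2] + cs[zc, "start"] - 1L):(b[2] + cs[zc, "end"] - 1L)
      truth[rows, cols] <- rig$plate_temp + rig$zone_offsets[zone]
    }
  }
  truth
}

#' Render a frame of the full measurement arrangement
#'
#' The validation plate behind the scene's reference patches (and face, if
#' any): the plate fills its block, then the scene's objects are drawn in
#' front. This is the frame the validation campaign measures.
#'
#' @param scene A [thermal_scene()] (reference patches in front).
#' @param rig A [validation_rig()] or `NULL`.
#' @param sensor A [sensor_model()].
#' @param timestamp Frame time (s).
#' @return A `thermal_frame`.
#' @export
render_subject_frame <- function(scene, rig, sensor, timestamp = 0) {
  truth <- matrix(scene$ambient, scene$grid_rows, scene$grid_cols)
  if (!is.null(rig)) truth <- overlay_rig(truth, rig)
  # face and patches sit in front of the plate
  if (!is.null(scene$face)) {
    f <- scene$face
    rows <- matrix(seq_len(scene$grid_rows), scene$grid_rows, scene$grid_cols)
    cols <- matrix(seq_len(scene$grid_cols), scene$grid_rows, scene$grid_cols,
                   byrow = TRUE)
    disc <- (rows - f$center[1])^2 + (cols - f$center[2])^2 <= f$radius^2
    truth[disc] <- f$temp
  }
  for (p in scene$peltier_patches) {
    truth[patch_rows(p), patch_cols(p)] <- p$plant$temp
  }
  new_thermal_frame(apply_sensor(truth, sensor, timestamp), timestamp)
}

#' Render a frame of the validation plate
#'
#' The plate block reads `plate_temp + zone_offset` through the sensor model;
#' everything else reads ambient. With `rig = NULL` the frame is all-ambient.
#'
#' @param rig A [validation_rig()] or `NULL`.
#' @param sensor A [sensor_model()].
#' @param ambient Background temperature (degC).
#' @param grid_rows,grid_cols Frame size.
#' @param timestamp Frame time (s).
#' @return A `thermal_frame`.
#' @export
render_validation_plate <- function(rig, sensor, ambient = 22,
                                    grid_rows = 24, grid_cols = 32,
                                    timestamp = 0) {
  truth <- matrix(ambient, grid_rows, grid_cols)
  if (!is.null(rig)) truth <- overlay_rig(truth, rig)
  new_thermal_frame(apply_sensor(truth, sensor, timestamp), timestamp)
}

#' Serialize frames to CSV
#'
#' Long format, one row per pixel: `frame_index,row,col,value`, with `row`
#' and `col` 0-based (row 0 = top), matching the documented external schema.
#'
#' @param frames List of `thermal_frame`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
frames_to_csv <- function(frames, path) {
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    data.frame(
      frame_index = i - 1L,
      row = rep(seq_len(nrow(fr)) - 1L, times = ncol(fr)),
      col = rep(seq_len(ncol(fr)) - 1L, each = nrow(fr)),
      value = as.vector(fr)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read frames back from CSV
#'
#' Inverse of [frames_to_csv()].
#'
#' @param path CSV path written by [frames_to_csv()].
#' @return List of numeric matrices (one per frame).
#' @export
frames_from_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(sort(unique(d$frame_index)), function(i) {
    di <- d[d$frame_index == i, ]
    m <- matrix(NA_real_, max(di$row) + 1L, max(di$col) + 1L)
    m[cbind(di$row + 1L, di$col + 1L)] <- di$value
    m
  })
}
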