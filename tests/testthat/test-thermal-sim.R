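# Thermal scene simulator: sensor model, PID/Peltier plant, warm-up frames,
# validation rig.

test_that("identity sensor renders the true scene temperatures", {
  sc <- thermal_scene(ambient = 30, face = NULL, peltier_patches = list())
  fr <- render_frame(sc, sensor_model(), timestamp = 0)
  expect_equal(dim(fr), c(24L, 32L))
  expect_true(all(fr == 30))
})

test_that("affine sensor error maps face pixels through gain and offset", {
  sc <- thermal_scene(face = list(center = c(17, 17), radius = 5, temp = 37),
                      peltier_patches = list())
  fr <- render_frame(sc, sensor_model(gain = 0.95, offset = -1.2))
  expect_equal(fr[17, 17], 0.95 * 37 - 1.2)  # 33.95, hand arithmetic
  expect_equal(fr[1, 1], 0.95 * 22 - 1.2)
})

test_that("scene invariants are enforced", {
  expect_error(
    thermal_scene(peltier_patches = list(
      peltier_patch(c(22L, 3L), 6L, 6L, peltier_plant(33)))),
    "outside"
  )
  expect_error(
    thermal_scene(peltier_patches = list(
      peltier_patch(c(5L, 4L), 6L, 6L, peltier_plant(33)),
      peltier_patch(c(8L, 7L), 6L, 6L, peltier_plant(38)))),
    "overlap"
  )
  expect_error(
    thermal_scene(face = list(center = c(17, 17), radius = 3, temp = 45)),
    "\\[30, 42\\]"
  )
  expect_error(pid_state(kp = NaN), "finite")
  expect_error(sensor_model(gain = 0), "gain")
})

test_that("PID contributes nothing at zero error and rest", {
  plant <- peltier_plant(setpoint = 30, temp = 30)
  st <- step_pid(plant, pid_state())
  expect_equal(st$duty, 0)
})

test_that("unheated plant stays at ambient equilibrium", {
  plant <- peltier_plant(setpoint = 22, temp = 22, ambient = 22)
  for (i in 1:50) plant <- step_plant(plant, 0, 0.5)
  expect_equal(plant$temp, 22)
})

test_that("constant-duty trajectory matches the discrete closed form", {
  for (duty in c(0.2, 0.44, 1.0)) {
    plant <- peltier_plant(setpoint = 40, temp = 22)
    n <- 400
    temps <- numeric(n)
    for (i in seq_len(n)) {
      plant <- step_plant(plant, duty, 0.5)
      temps[i] <- plant$temp
    }
    t_inf <- 22 + plant$k_heat * duty / plant$k_loss
    closed <- t_inf + (22 - t_inf) * (1 - plant$k_loss * 0.5)^(seq_len(n))
    expect_lt(max(abs(temps - closed)), 1e-6)
  }
})

test_that("default PID settles both reference setpoints within the band", {
  for (sp in c(33, 38)) {
    tr <- simulate_plant(peltier_plant(sp), pid_state(), duration = 400)
    expect_lte(max(abs(tr$temp[tr$time > 300] - sp)), 0.1)
    # warm-up completes well inside the two-minute calibration phase
    expect_lt(abs(tr$temp[tr$time == 120] - sp), 0.1)
  }
})

test_that("warm-up frames end with patches at their setpoints", {
  frames <- default_warmup()
  expect_length(frames, 120)
  last <- frames[[length(frames)]]
  sc <- attr(frames, "scene")
  means <- vapply(sc$peltier_patches, function(p) {
    mean(last[feverwatch:::patch_rows(p), feverwatch:::patch_cols(p)])
  }, numeric(1))
  expect_lt(abs(min(means) - 33), 0.2)
  expect_lt(abs(max(means) - 38), 0.2)
  expect_error(simulate_warmup(thermal_scene(), sensor_model(), duration = 0),
               "at least one frame_period")
})

test_that("frame sequences are bit-identical under a fixed seed", {
  sen <- sensor_model(noise_sd = 0.3, seed = 99L)
  f1 <- simulate_warmup(thermal_scene(), sen, duration = 30)
  f2 <- simulate_warmup(thermal_scene(), sen, duration = 30)
  expect_identical(f1, f2)
  f3 <- simulate_warmup(thermal_scene(), sensor_model(noise_sd = 0.3,
                                                      seed = 100L),
                        duration = 30)
  expect_false(identical(f1, f3))
})

test_that("validation plate renders zone temperatures through the sensor", {
  rig <- validation_rig(37.81)
  fr <- render_validation_plate(rig, sensor_model())
  expect_true(all(abs(fr - 37.81) < 1e-12))

  offs <- c(0.1, -0.1, 0.05, 0, -0.05, 0.1, -0.1, 0, 0.05)
  rig2 <- validation_rig(37, zone_offsets = offs,
                         plate_block = c(4L, 5L, 12L, 12L))
  fr2 <- render_validation_plate(rig2, sensor_model(noise_sd = 0.05, seed = 4))
  for (zr in 1:3) for (zc in 1:3) {
    rows <- 4L + (zr - 1L) * 4L + 0:3
    cols <- 5L + (zc - 1L) * 4L + 0:3
    zone_mean <- mean(fr2[rows, cols])
    expect_lt(abs(zone_mean - (37 + offs[(zr - 1) * 3 + zc])), 0.05)
  }

  empty <- render_validation_plate(NULL, sensor_model(), ambient = 22)
  expect_true(all(empty == 22))
  expect_error(validation_rig(37, zone_offsets = rep(0.9, 9)), "uniformity")
  expect_error(
    render_validation_plate(validation_rig(37, plate_block = c(20L, 1L, 12L, 12L)),
                            sensor_model()),
    "outside the grid")
})

test_that("frame CSV serialization round-trips", {
  frames <- simulate_warmup(thermal_scene(), sensor_model(noise_sd = 0.1),
                            duration = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  frames_to_csv(frames, path)
  back <- frames_from_csv(path)
  expect_length(back, 3)
  for (i in 1:3) expect_equal(back[[i]], unclass(frames[[i]]),
                              ignore_attr = TRUE)
  # documented schema: 0-based pixel indices
  d <- utils::read.csv(path)
  expect_equal(range(d$row), c(0, 23))
  expect_equal(range(d$col), c(0, 31))
})
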