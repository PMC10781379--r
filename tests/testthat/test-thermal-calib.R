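# Reference self-detection, two-point calibration, patient location and the
# validation campaign.

test_that("reference regions are recovered exactly from a noise-free warm-up", {
  frames <- default_warmup()
  regions <- detect_peltier_regions(frames, 33, 38)
  sc <- attr(frames, "scene")
  truth_low <- matrix(FALSE, 24, 32)
  truth_high <- truth_low
  p_low <- sc$peltier_patches[[1]]  # 33 degC patch
  p_high <- sc$peltier_patches[[2]]
  truth_low[feverwatch:::patch_rows(p_low), feverwatch:::patch_cols(p_low)] <- TRUE
  truth_high[feverwatch:::patch_rows(p_high), feverwatch:::patch_cols(p_high)] <- TRUE
  expect_identical(regions$low_pixels, truth_low)
  expect_identical(regions$high_pixels, truth_high)
  # exclusion mask contains both regions (dilated)
  expect_true(all(regions$exclusion_mask[truth_low | truth_high]))
  expect_gt(sum(regions$exclusion_mask), sum(truth_low) + sum(truth_high))
})

test_that("a static scene yields a references-not-found error", {
  sc <- thermal_scene(face = list(center = c(17, 17), radius = 5, temp = 37),
                      peltier_patches = list())
  frames <- lapply(1:20, function(i) render_frame(sc, sensor_model(), i))
  expect_error(detect_peltier_regions(frames, 33, 38), "references not found")
  expect_error(detect_peltier_regions(frames[1:5], 33, 38), "at least 10")
  expect_error(detect_peltier_regions(frames, 38, 33), "ref_low")
})

test_that("noisy warm-up still recovers the reference regions (Jaccard >= 0.8)", {
  sen <- sensor_model(noise_sd = 0.2, seed = 7L)
  frames <- simulate_warmup(thermal_scene(), sen, duration = 120)
  regions <- detect_peltier_regions(frames, 33, 38)
  sc <- attr(frames, "scene")
  for (k in 1:2) {
    p <- sc$peltier_patches[[k]]
    truth <- matrix(FALSE, 24, 32)
    truth[feverwatch:::patch_rows(p), feverwatch:::patch_cols(p)] <- TRUE
    found <- if (k == 1) regions$low_pixels else regions$high_pixels
    jaccard <- sum(truth & found) / sum(truth | found)
    expect_gte(jaccard, 0.8)
  }
})

test_that("two-point calibration is exact at its anchors", {
  cc <- fit_calibration(31, 33, 36, 38)
  expect_equal(cc$slope, 1.0)
  expect_equal(cc$intercept, 2.0)
  expect_equal(apply_calibration(cc, 31), 33)

  ident <- fit_calibration(33, 33, 38, 38)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)

  # anchor exactness for random anchor pairs
  set.seed(11)
  for (i in 1:50) {
    r <- sort(runif(2, 20, 40))
    t <- sort(runif(2, 30, 40))
    cc <- fit_calibration(r[1], t[1], r[2], t[2])
    expect_lt(abs(apply_calibration(cc, r[1]) - t[1]), 1e-12)
    expect_lt(abs(apply_calibration(cc, r[2]) - t[2]), 1e-12)
  }
})

test_that("calibration inverts an affine sensor and rejects degenerate anchors", {
  g <- 0.93; b <- 1.7
  cc <- fit_calibration(g * 33 + b, 33, g * 38 + b, 38)
  expect_lt(abs(cc$slope - 1 / g), 1e-9)
  expect_lt(abs(cc$intercept - (-b / g)), 1e-9)

  expect_error(fit_calibration(35, 33, 35, 38), "degenerate")
  expect_error(fit_calibration(36, 33, 31, 38), "inverted")
})

test_that("corrected temperature is strictly increasing in the raw reading", {
  set.seed(5)
  for (i in 1:20) {
    cc <- fit_calibration(30, runif(1, 31, 35), 40, runif(1, 36, 41))
    raws <- sort(runif(10, 20, 45))
    expect_true(all(diff(apply_calibration(cc, raws)) > 0))
  }
})

test_that("locate_patient agrees with an exhaustive row-major scan", {
  argmax_oracle <- function(vals, mask) {
    best <- -Inf; at <- NULL
    for (r in seq_len(nrow(vals))) for (cc in seq_len(ncol(vals))) {
      if (!is.null(mask) && mask[r, cc]) next
      if (vals[r, cc] > best) { best <- vals[r, cc]; at <- c(r, cc) }
    }
    at
  }
  set.seed(21)
  for (i in 1:200) {
    vals <- matrix(sample(seq(20, 40, by = 0.5), 24 * 32, replace = TRUE),
                   24, 32)
    mask <- if (i %% 2 == 0) matrix(runif(24 * 32) < 0.2, 24, 32) else NULL
    if (!is.null(mask) && all(mask)) next
    expect_equal(unname(locate_patient(vals, mask)),
                 argmax_oracle(vals, mask))
  }
})

test_that("exclusion and tie-break semantics hold", {
  fr <- matrix(22, 24, 32)
  fr[11, 6] <- 39
  expect_equal(unname(locate_patient(fr, NULL)), c(11, 6))

  fr[3, 3] <- 40  # hotter but excluded
  mask <- matrix(FALSE, 24, 32); mask[3, 3] <- TRUE
  expect_equal(unname(locate_patient(fr, mask)), c(11, 6))

  uni <- matrix(30, 24, 32)
  expect_equal(unname(locate_patient(uni, NULL)), c(1, 1))
  expect_error(locate_patient(uni, matrix(TRUE, 24, 32)), "excluded")
})

test_that("patient temperature averages the 3x3 neighbourhood", {
  ident <- fit_calibration(33, 33, 38, 38)
  uni <- matrix(37, 24, 32)
  expect_equal(patient_temperature(uni, c(10, 10), ident)$corrected, 37)

  fr <- matrix(37, 24, 32)
  fr[10, 10] <- 38
  expect_equal(patient_temperature(fr, c(10, 10), ident)$corrected, 334 / 9)

  corner <- matrix(22, 24, 32)
  corner[1:2, 1:2] <- c(35, 36, 37, 38)
  expect_equal(patient_temperature(corner, c(1, 1), ident)$raw_mean,
               mean(c(35, 36, 37, 38)))
  expect_error(patient_temperature(fr, c(0, 5), ident), "outside")
})

test_that("affine sensor error cancels end to end (parameter recovery)", {
  camp <- run_validation_campaign(c(36.5, 37.81, 38.5),
                                  sensor_model(gain = 0.97, offset = 0.5))
  expect_lt(max(camp$error_C), 1e-9)

  # the full pipeline (warm-up, detection, calibration, measurement)
  # recovers the subject temperature for any gain/offset sensor
  for (g in c(0.9, 1.05)) {
    sen <- sensor_model(gain = g, offset = -2.1)
    fr_cal <- simulate_warmup(thermal_scene(), sen, duration = 120)
    warm <- attr(fr_cal, "scene")
    refs <- feverwatch:::reference_readings(warm)
    reg <- detect_peltier_regions(fr_cal, refs["low"], refs["high"])
    reading <- measure_patient(
      render_subject_frame(warm, validation_rig(37.4), sen, 200), reg)
    expect_lt(abs(reading$corrected - 37.4), 1e-9)
  }
})

test_that("noisy campaign keeps the mean absolute error small", {
  tbl <- prototype_validation_table()
  camp <- run_validation_campaign(
    unique(tbl$validation_C),
    sensor_model(gain = 0.97, offset = 0.5, noise_sd = 0.2, seed = 13L),
    repetitions = 3)
  expect_lte(mean(camp$error_C), 0.4)
  expect_true(all(camp$error_C == abs(camp$measured_C - camp$validation_C)))
  # CSV interface mirrors the bench-table format
  path <- withr::local_tempfile(fileext = ".csv")
  run_validation_campaign(c(37, 38), sensor_model(), csv = path)
  expect_equal(names(utils::read.csv(path)),
               c("measured_C", "validation_C", "error_C"))
  expect_error(run_validation_campaign(50, sensor_model()), "\\[30, 42\\]")
})
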