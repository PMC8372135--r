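test_that("reference correction computes (scan-dark)/(white-dark) for VIS/NIR", {
  w <- c(500, 600)
  scan <- spectrum("VIS", w, c(30, 40))
  dark <- spectrum("VIS", w, c(10, 10))
  white <- spectrum("VIS", w, c(50, 40))
  expect_equal(reference_correct(scan, dark, white)$intensities, c(0.5, 1.0))

  # ratio identities: scan == white -> 1, scan == dark -> 0
  expect_equal(reference_correct(white, dark, white)$intensities, c(1, 1))
  expect_equal(reference_correct(dark, dark, white)$intensities, c(0, 0))
})

test_that("FLUO correction is dark-only and rejects a white reference", {
  w <- c(400, 500, 600)
  scan <- spectrum("FLUO", w, c(100, 250, 90))
  dark <- spectrum("FLUO", w, c(10, 20, 30))
  expect_equal(reference_correct(scan, dark)$intensities, c(90, 230, 60))
  expect_error(reference_correct(scan, dark, spectrum("FLUO", w, c(1, 1, 1))),
               class = "grid_error")
  # VIS/NIR conversely require white
  expect_error(reference_correct(spectrum("VIS", w, c(1, 2, 3)),
                                 spectrum("VIS", w, c(0, 0, 0))),
               class = "grid_error")
})

test_that("reference correction rejects mismatched grids and dead references", {
  a <- spectrum("VIS", c(500, 600), c(1, 2))
  b <- spectrum("VIS", c(500, 601), c(0, 0))
  expect_error(reference_correct(a, b, a), class = "grid_error")
  dark <- spectrum("VIS", c(500, 600), c(10, 10))
  white_dead <- spectrum("VIS", c(500, 600), c(10, 50))
  expect_error(reference_correct(a, dark, white_dead),
               class = "degenerate_reference_error")
})

test_that("VIS/NIR correction is invariant to detector gain", {
  w <- seq(400, 700, length.out = 50)
  withr::with_seed(11, {
    scan <- runif(50, 100, 200); dark <- runif(50, 5, 15)
    white <- scan + runif(50, 50, 80)
  })
  ref <- reference_correct(spectrum("VIS", w, scan), spectrum("VIS", w, dark),
                           spectrum("VIS", w, white))$intensities
  for (c_gain in c(0.5, 3, 1e4)) {
    scaled <- reference_correct(spectrum("VIS", w, c_gain * scan),
                                spectrum("VIS", w, c_gain * dark),
                                spectrum("VIS", w, c_gain * white))$intensities
    expect_equal(scaled, ref, tolerance = 1e-12)
  }
})

test_that("trimming keeps a closed interval and is idempotent", {
  nir <- spectrum("NIR", 939:1833, seq_len(895))
  tr <- trim_spectrum(nir, 1020, 1833)
  expect_length(tr$wavelengths, 814)
  expect_equal(range(tr$wavelengths), c(1020, 1833))
  expect_equal(trim_spectrum(nir, 939, 1833)$intensities, nir$intensities)
  expect_equal(trim_spectrum(tr, 1020, 1833), tr)
  expect_error(trim_spectrum(spectrum("VIS", c(400, 500), c(1, 2)), 450, 460),
               class = "empty_trim_error")
})

test_that("saturation detection requires a long-enough plateau", {
  w <- seq(400, 430, by = 10)
  expect_false(detect_saturation(spectrum("VIS", w, c(1, 2, 3, 4)), 9, 1))
  expect_true(detect_saturation(spectrum("VIS", w, c(1, 9, 9, 9)), 9, 3))
  expect_false(detect_saturation(c(1, 9, 9, 1), 9, 3))
  expect_true(detect_saturation(c(1, 9, 9, 1), 9, 2))
})

test_that("saturation detection matches a brute-force run-length oracle", {
  brute <- function(x, lvl, k) {
    any(vapply(seq_len(length(x) - k + 1L),
               function(i) all(x[i:(i + k - 1L)] >= lvl), TRUE))
  }
  withr::with_seed(42, {
    for (rep in 1:50) {
      x <- sample(c(1, 5, 9, 10), 12, replace = TRUE)
      k <- sample(1:4, 1)
      expect_identical(detect_saturation(x, 9, k), brute(x, 9, k))
    }
  })
})

make_run <- function(scans, dark = NULL, sensor = "FLUO", w = NULL) {
  p <- ncol(scans)
  w <- w %||% seq(400, 700, length.out = p)
  measurement_run("S1", 1, 1, scans = setNames(list(scans), sensor),
                  dark = setNames(list(dark %||% numeric(p)), sensor),
                  white = list(), grids = setNames(list(w), sensor))
}

test_that("scan averaging is the pointwise mean of retained scans", {
  m <- matrix(rep(c(1, 5, 2), 10), nrow = 10, byrow = TRUE)
  expect_equal(average_scans(make_run(m), "FLUO")$intensities, c(1, 5, 2))
  two <- rbind(c(0, 2), c(2, 0))
  expect_equal(average_scans(make_run(two, w = c(1, 2)), "FLUO")$intensities,
               c(1, 1))
  expect_error(average_scans(make_run(two, w = c(1, 2)), "FLUO",
                             discard = c(TRUE, TRUE)),
               class = "empty_measurement_error")
})

test_that("averaging 255 noisy scans concentrates at the true mean", {
  mu <- c(10, 50, 20, 80); sigma <- 4
  scans <- withr::with_seed(5,
    matrix(rnorm(255 * 4, rep(mu, each = 255), sigma), nrow = 255))
  avg <- average_scans(make_run(scans, w = 1:4), "FLUO")$intensities
  expect_true(all(abs(avg - mu) < 4 * sigma / sqrt(255)))
})

test_that("scan averaging commutes with pointwise affine maps", {
  scans <- withr::with_seed(8, matrix(runif(30), nrow = 6))
  a <- 2.5; b <- -3
  lhs <- average_scans(make_run(a * scans + b, w = 1:5), "FLUO")$intensities
  rhs <- a * average_scans(make_run(scans, w = 1:5), "FLUO")$intensities + b
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("saturation filter removes flagged entries and conserves counts", {
  entry <- function(i, sensor, sat) list(
    sample_id = paste0("S", i), sensor = sensor,
    spectrum = spectrum(sensor, c(1, 2), c(0, 0), saturated = sat))
  ms <- c(lapply(1:1161, function(i) entry(i, "FLUO", i <= 122)),
          lapply(1:1161, function(i) entry(i, "VIS", i <= 90)))
  res <- filter_saturated(ms)
  expect_equal(sum(vapply(res$retained, function(e) e$sensor == "FLUO", TRUE)),
               1039)
  expect_equal(res$removed_counts[["FLUO"]], 122)
  expect_equal(res$removed_counts[["VIS"]], 90)
  expect_equal(res$input_counts - res$removed_counts,
               c(FLUO = 1039L, VIS = 1071L))

  none <- filter_saturated(lapply(1:5, function(i) entry(i, "VIS", FALSE)))
  expect_length(none$retained, 5)
  all_f <- filter_saturated(lapply(1:5, function(i) entry(i, "VIS", TRUE)))
  expect_length(all_f$retained, 0)
  expect_equal(all_f$removed_counts[["VIS"]], 5L)
})

test_that("process_run flags a sensor-level saturated measurement", {
  sensors <- small_sensors()
  g <- sensor_grid(sensors$FLUO)
  run <- measurement_run("S1", 1, 1,
                         scans = list(FLUO = matrix(65535, 4, length(g))),
                         dark = list(FLUO = numeric(length(g))),
                         white = list(),
                         grids = list(FLUO = g))
  out <- process_run(run, sensors)
  expect_true(out$FLUO$spectrum$saturated)
})
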