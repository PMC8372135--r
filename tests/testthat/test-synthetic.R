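test_that("the oil library matches the design counts and class structure", {
  d <- small_design()
  lib <- generate_oil_library(d)
  expect_equal(nrow(lib$samples), 8 + 5 + 3 + 5)
  expect_equal(sum(lib$samples$oil_class == "EVOO"), 8)
  expect_false(any(lib$samples$adulterated))
  expect_setequal(names(lib$latents), lib$samples$sample_id)
  expect_named(lib$latents[[1]], c("FLUO", "VIS", "NIR"))
})

test_that("zero between-sample CV collapses each class to its archetype", {
  d <- small_design(cv_scale = 0)
  lib <- generate_oil_library(d)
  evoo <- lib$samples$sample_id[lib$samples$oil_class == "EVOO"]
  for (id in evoo[-1])
    expect_identical(lib$latents[[id]], lib$latents[[evoo[1]]])
})

test_that("q-band peak variability reproduces the configured CV", {
  d <- small_design(n_evoo = 1000L, n_rvoo = 0L, n_opo = 0L, n_other = 0L,
                    n_mix_olive = 0L, n_mix_other = 0L,
                    n_saturated_fluo = 0L, n_saturated_vis = 0L)
  lib <- generate_oil_library(d)
  g <- sensor_grid(d$sensors$FLUO)
  qpix <- which.min(abs(g - 672))
  peaks <- vapply(lib$latents, function(l) l$FLUO[qpix], 0)
  cv_emp <- sd(peaks) / mean(peaks)
  cv_cfg <- oil_archetypes()$EVOO$between_sample_cv
  expect_lt(abs(cv_emp - cv_cfg) / cv_cfg, 0.10)
})

test_that("admixtures mix latent spectra linearly in the volume fraction", {
  d <- small_design()
  lib <- generate_oil_library(d)
  adm <- generate_admixtures(lib, d)
  expect_equal(nrow(adm$samples), 4 + 6)
  expect_true(all(adm$samples$adulterated))
  expect_true(all(adm$samples$oil_class == "EVOO"))
  expect_true(all(adm$samples$fraction_v %in% c(0.10, 0.25, 0.50)))
  expect_setequal(unique(adm$samples$adulterant_class),
                  c("OLIVE_NON_EVOO", "OTHER_OIL"))

  a <- lib$latents[["EVOO01"]]; b <- lib$latents[["OTH01"]]
  mid <- mix_latents(a, b, 0.5)
  expect_equal(mid$FLUO, (a$FLUO + b$FLUO) / 2)
  # strict betweenness and exact linearity wherever the endpoints differ
  for (f in c(0.1, 0.3, 0.9)) {
    m <- mix_latents(a, b, f)$FLUO
    expect_equal(m, (1 - f) * a$FLUO + f * b$FLUO)
    diff_pts <- abs(a$FLUO - b$FLUO) > 1e-9
    lo <- pmin(a$FLUO, b$FLUO)[diff_pts]; hi <- pmax(a$FLUO, b$FLUO)[diff_pts]
    expect_true(all(m[diff_pts] > lo & m[diff_pts] < hi))
  }
  # manifest bookkeeping: base and adulterant recorded and reproducible
  first <- adm$samples[1, ]
  expect_equal(adm$latents[[first$sample_id]]$VIS,
               mix_latents(lib$latents[[first$base_id]],
                           lib$latents[[first$adulterant_id]],
                           first$fraction_v)$VIS)
  no_pool <- small_design(n_other = 0L)
  expect_error(generate_admixtures(generate_oil_library(no_pool), no_pool),
               class = "design_error")
})

test_that("simulated runs are deterministic and invert under correction", {
  id <- "EVOO01"
  dn <- small_design()
  libn <- generate_oil_library(dn)
  r1 <- simulate_run(id, libn$latents[[id]], 2, 1, dn)
  r2 <- simulate_run(id, libn$latents[[id]], 2, 1, dn)
  expect_identical(r1, r2)
  r3 <- simulate_run(id, libn$latents[[id]], 2, 2, dn)
  expect_false(identical(r1$scans$FLUO, r3$scans$FLUO))

  # noiseless, drift-free runs invert exactly under reference correction
  d <- small_design(noise_sd = c(FLUO = 0, VIS = 0, NIR = 0), drift = 0)
  lib <- generate_oil_library(d)
  r0 <- simulate_run(id, lib$latents[[id]], 2, 1, d)
  pr <- process_run(r0, d$sensors, sat_level = d$sat_level)
  for (s in c("FLUO", "VIS", "NIR")) {
    sk <- d$sensors[[s]]
    latent_used <- trim_spectrum(
      spectrum(s, sensor_grid(sk), lib$latents[[id]][[s]]),
      sk$used_range_nm[1], sk$used_range_nm[2])$intensities
    expect_equal(pr[[s]]$spectrum$intensities, latent_used,
                 tolerance = 1e-10)
  }
})

test_that("corrected scan noise matches the configured magnitude", {
  d <- small_design(drift = 0, scans_per_run = c(VIS = 3L, FLUO = 3L,
                                                 NIR = 255L))
  lib <- generate_oil_library(d)
  run <- simulate_run("EVOO02", lib$latents[["EVOO02"]], 1, 1, d)
  denom <- run$white$NIR - run$dark$NIR
  corrected <- sweep(sweep(run$scans$NIR, 2, run$dark$NIR), 2, denom, "/")
  sd_emp <- apply(corrected, 2, sd)
  sd_exp <- d$noise_sd[["NIR"]] / abs(denom)
  expect_lt(max(abs(sd_emp - sd_exp) / sd_exp), 0.15)
})

test_that("the full study honours the design bookkeeping and manifest", {
  st <- small_study()
  d <- st$design
  n_samples <- 8 + 5 + 3 + 5 + 4 + 6
  expect_equal(st$counts$n_samples, n_samples)
  expect_equal(st$counts$n_runs, n_samples * 3)
  expect_equal(unname(st$counts$scans[c("VIS", "FLUO", "NIR")]),
               n_samples * 3 * c(3, 3, 5))
  # every run appears exactly once in the manifest
  expect_equal(nrow(unique(st$run_manifest[, c("sample_id", "day",
                                               "within_day")])),
               st$counts$n_runs)
  # injected saturation counts are exact and the filter fires on them
  expect_equal(sum(st$run_manifest$sat_fluo), 4)
  expect_equal(sum(st$run_manifest$sat_vis), 3)
  ret <- retained_measurements(st)
  expect_equal(unname(ret$removed_counts[c("FLUO", "VIS", "NIR")]),
               c(4L, 3L, 0L))
  expect_equal(ret$input_counts - ret$removed_counts,
               setNames(st$counts$n_runs - c(3L, 4L, 0L),
                        c("VIS", "FLUO", "NIR")))
  # flags land exactly on the injected runs
  expect_equal(st$measurements$FLUO$meta$saturated, st$run_manifest$sat_fluo)
  expect_equal(st$measurements$VIS$meta$saturated, st$run_manifest$sat_vis)
})

test_that("keep_scans retains raw runs identical to the streamed reduction", {
  d <- small_design(n_evoo = 2L, n_rvoo = 1L, n_opo = 0L, n_other = 1L,
                    n_mix_olive = 0L, n_mix_other = 1L,
                    n_saturated_fluo = 1L, n_saturated_vis = 0L)
  st <- generate_study(d, keep_scans = TRUE)
  expect_length(st$runs, st$counts$n_runs)
  i <- 3L
  pr <- process_run(st$runs[[i]], d$sensors, sat_level = d$sat_level)
  expect_equal(pr$NIR$spectrum$intensities, st$measurements$NIR$X[i, ])
  expect_equal(pr$FLUO$spectrum$saturated,
               st$measurements$FLUO$meta$saturated[i])
})

test_that("with no variability the FLUO q-band separates classes perfectly", {
  d <- small_design(cv_scale = 0, noise_sd = c(FLUO = 0, VIS = 0, NIR = 0),
                    drift = 0, n_saturated_fluo = 0L, n_saturated_vis = 0L)
  st <- generate_study(d)
  g <- st$measurements$FLUO$wavelengths
  qpix <- which.min(abs(g - 672))
  peak <- st$measurements$FLUO$X[, qpix]
  truth <- setNames(st$samples$truth_class, st$samples$sample_id)
  cls <- truth[st$measurements$FLUO$meta$sample_id]
  # inverted peak height as a class distance: EVOO has the tallest q-band
  expect_equal(auroc(-peak[cls == "EVOO"], -peak[cls == "OTHER"]), 1.0)
})
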