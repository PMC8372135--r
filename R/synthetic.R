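#' Study design for the synthetic oil-authentication study
#'
#' Defaults reproduce the measurement design the pipeline was built for:
#' 16 EVOO, 32 RVOO, 9 OPO and 12 other edible oils; 20 EVOO admixtures with
#' non-EVOO olive oils and 40 with other edible oils at 10/25/50% (v/v);
#' nine replicate measurement runs per sample (triplicate on each of three
#' days); 10 VIS + 10 FLUO + 255 NIR scans per run; and 122 FLUO / 90 VIS
#' measurements rendered saturated so the saturation filter fires. Noise and
#' drift magnitudes are free parameters of the generator (the instrument's
#' values are not documented anywhere), exposed here with defaults chosen to
#' give a realistic but solvable classification problem.
#'
#' @param n_evoo,n_rvoo,n_opo,n_other pure-oil counts per class.
#' @param n_mix_olive,n_mix_other admixture counts (EVOO adulterated with
#'   RVOO/OPO, resp. other edible oils).
#' @param mix_levels adulteration volume fractions sampled for admixtures.
#' @param n_replicates measurement runs per sample (spread over 3 days).
#' @param scans_per_run named integer vector of scans per sensor per run.
#' @param n_saturated_fluo,n_saturated_vis number of measurement runs whose
#'   FLUO resp. VIS scans are clipped at the detector ceiling.
#' @param seed root seed; all randomness derives from it.
#' @param sensors sensor set (see [default_sensors()]).
#' @param noise_sd per-sensor additive Gaussian scan noise (detector counts).
#' @param drift half-width of the per-(sample, day) uniform multiplicative
#'   drift factor modelling storage degradation (default 2%).
#' @param sat_level detector ceiling (counts).
#' @param sat_gain over-exposure gain applied to runs chosen for saturation.
#' @param dark_level mean dark-current level (counts).
#' @param vis_baseline,nir_baseline latent transflectance baselines.
#' @param cv_scale global multiplier on the between-sample band CVs (0 makes
#'   all oils of a class identical).
#' @param archetypes class archetypes (see [oil_archetypes()]).
#' @return list of class `study_design`.
#' @export
study_design <- function(n_evoo = 16L, n_rvoo = 32L, n_opo = 9L,
                         n_other = 12L, n_mix_olive = 20L, n_mix_other = 40L,
                         mix_levels = c(0.10, 0.25, 0.50), n_replicates = 9L,
                         scans_per_run = c(VIS = 10L, FLUO = 10L, NIR = 255L),
                         n_saturated_fluo = 122L, n_saturated_vis = 90L,
                         seed = 1L, sensors = default_sensors(),
                         noise_sd = c(FLUO = 30, VIS = 40, NIR = 40),
                         drift = 0.02, sat_level = 65535, sat_gain = 40,
                         dark_level = 800, vis_baseline = 0.85,
                         nir_baseline = 0.75, cv_scale = 1,
                         archetypes = oil_archetypes()) {
  d <- list(n_evoo = n_evoo, n_rvoo = n_rvoo, n_opo = n_opo,
            n_other = n_other, n_mix_olive = n_mix_olive,
            n_mix_other = n_mix_other, mix_levels = mix_levels,
            n_replicates = as.integer(n_replicates),
            scans_per_run = scans_per_run,
            n_saturated_fluo = as.integer(n_saturated_fluo),
            n_saturated_vis = as.integer(n_saturated_vis),
            seed = as.integer(seed), sensors = sensors, noise_sd = noise_sd,
            drift = drift, sat_level = sat_level, sat_gain = sat_gain,
            dark_level = dark_level, vis_baseline = vis_baseline,
            nir_baseline = nir_baseline, cv_scale = cv_scale,
            archetypes = archetypes)
  stopifnot(all(unlist(d[1:6]) >= 0), n_evoo >= 1L, n_replicates >= 1L,
            all(mix_levels > 0), all(mix_levels < 1),
            all(scans_per_run >= 1L), drift >= 0, cv_scale >= 0)
  n_runs <- (n_evoo + n_rvoo + n_opo + n_other + n_mix_olive + n_mix_other) *
    d$n_replicates
  if (d$n_saturated_fluo > n_runs || d$n_saturated_vis > n_runs)
    stop_evoofuse("more saturated measurements requested than runs",
                  "design_error")
  structure(d, class = "study_design")
}

#' Generate the pure-oil library with latent spectra
#'
#' One latent noiseless spectrum per (oil, sensor), drawn by perturbing the
#' class archetype's band amplitudes with lognormal factors of the class's
#' between-sample CV.
#'
#' @param design a [study_design()].
#' @return list with `samples` (data frame: `sample_id`, `oil_class`,
#'   `truth_class`, `adulterated`, admixture fields all `NA`) and `latents`
#'   (named list: sample id -> per-sensor latent spectra on the raw grids).
#' @export
generate_oil_library <- function(design) {
  classes <- c(EVOO = design$n_evoo, RVOO = design$n_rvoo,
               OPO = design$n_opo, OTHER = design$n_other)
  prefix <- c(EVOO = "EVOO", RVOO = "RVOO", OPO = "OPO", OTHER = "OTH")
  rows <- list(); latents <- list()
  for (cl in names(classes)) {
    for (i in seq_len(classes[[cl]])) {
      id <- sprintf("%s%02d", prefix[[cl]], i)
      latents[[id]] <- withr::with_seed(derive_seed(design$seed, "oil", id),
                                        draw_latents(cl, design))
      rows[[id]] <- data.frame(sample_id = id, oil_class = cl,
                               truth_class = cl, adulterated = FALSE,
                               base_id = NA_character_,
                               adulterant_id = NA_character_,
                               adulterant_class = NA_character_,
                               fraction_v = NA_real_,
                               stringsAsFactors = FALSE)
    }
  }
  list(samples = bind_sample_rows(rows), latents = latents)
}

bind_sample_rows <- function(rows) {
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Generate EVOO admixtures by linear volume mixing
#'
#' Base EVOO, adulterant and level are drawn uniformly under the design seed;
#' the latent admixture spectrum is `(1 - f) * base + f * adulterant` per
#' sensor (linear volume mixing; fluorescence inner-filter effects are a
#' known simplification).
#'
#' @param library output of [generate_oil_library()].
#' @param design a [study_design()].
#' @return same shape as [generate_oil_library()], admixture samples only
#'   (truth classes `ADULT_OLIVE` / `ADULT_OTHER`).
#' @export
generate_admixtures <- function(library, design) {
  smp <- library$samples
  evoo <- smp$sample_id[smp$oil_class == "EVOO"]
  pools <- list(
    ADULT_OLIVE = smp$sample_id[smp$oil_class %in% c("RVOO", "OPO")],
    ADULT_OTHER = smp$sample_id[smp$oil_class == "OTHER"])
  counts <- c(ADULT_OLIVE = design$n_mix_olive,
              ADULT_OTHER = design$n_mix_other)
  prefix <- c(ADULT_OLIVE = "MIXO", ADULT_OTHER = "MIXE")
  rows <- list(); latents <- list()
  for (tc in names(counts)) {
    if (counts[[tc]] > 0L && !length(pools[[tc]]))
      stop_evoofuse(paste("empty adulterant pool for", tc), "design_error")
    if (counts[[tc]] > 0L && !length(evoo))
      stop_evoofuse("no EVOO base oils available", "design_error")
    for (i in seq_len(counts[[tc]])) {
      id <- sprintf("%s%02d", prefix[[tc]], i)
      draw <- withr::with_seed(derive_seed(design$seed, "mix", id), list(
        base = sample(evoo, 1L), adt = sample(pools[[tc]], 1L),
        f = sample(design$mix_levels, 1L)))
      adulterant_cl <- if (tc == "ADULT_OLIVE") "OLIVE_NON_EVOO" else
        "OTHER_OIL"
      latents[[id]] <- mix_latents(library$latents[[draw$base]],
                                   library$latents[[draw$adt]], draw$f)
      rows[[id]] <- data.frame(sample_id = id, oil_class = "EVOO",
                               truth_class = tc, adulterated = TRUE,
                               base_id = draw$base,
                               adulterant_id = draw$adt,
                               adulterant_class = adulterant_cl,
                               fraction_v = draw$f, stringsAsFactors = FALSE)
    }
  }
  list(samples = bind_sample_rows(rows), latents = latents)
}

#' Linear volume mixing of two latent spectra sets
#' @param base,adulterant per-sensor latent spectra lists.
#' @param f adulterant volume fraction in (0, 1).
#' @return per-sensor mixed latent spectra.
#' @export
mix_latents <- function(base, adulterant, f) {
  stopifnot(f > 0, f < 1)
  stats::setNames(lapply(names(base), function(s)
    (1 - f) * base[[s]] + f * adulterant[[s]]), names(base))
}

# smooth illumination profile of the VIS/NIR light path (counts)
illum_profile <- function(sensor, grid) {
  switch(sensor,
         VIS = 20000 * exp(-((grid - 550) / 250)^2) + 6000,
         NIR = 18000 * exp(-((grid - 1350) / 400)^2) + 5000,
         stop_evoofuse("no illumination profile for sensor", "sensor_error"))
}

dark_profile <- function(design, grid) {
  design$dark_level + 0.02 * (grid - min(grid))
}

#' Simulate one measurement run
#'
#' Emits the dark reference (baseline + noise), the white reference (VIS and
#' NIR only) and the per-sensor scan sets. A VIS/NIR scan is
#' `dark + drift * latent * illumination + noise`; a FLUO scan is
#' `dark + drift * latent + noise` (emission counts, no white path). The
#' multiplicative drift factor is drawn once per (sample, day), modelling
#' storage degradation over the measurement campaign. Runs chosen for
#' saturation are over-exposed by `sat_gain` and clipped at the detector
#' ceiling. Deterministic given (design seed, sample id, replicate).
#'
#' @param sample_id sample identifier (keyed into `latents`).
#' @param latents per-sensor latent spectra of this sample (raw grids).
#' @param day,within_day replicate coordinates (1-3 each).
#' @param design a [study_design()].
#' @param saturate named logical, e.g. `c(FLUO = TRUE, VIS = FALSE)`.
#' @return a [measurement_run()].
#' @export
simulate_run <- function(sample_id, latents, day, within_day, design,
                         saturate = c(FLUO = FALSE, VIS = FALSE)) {
  drift <- withr::with_seed(
    derive_seed(design$seed, "drift", sample_id, day),
    1 + stats::runif(1, -design$drift, design$drift))
  withr::with_seed(
    derive_seed(design$seed, "run", sample_id, day, within_day), {
      grids <- lapply(design$sensors, sensor_grid)
      scans <- dark <- white <- list()
      for (s in names(design$scans_per_run)) {
        g <- grids[[s]]
        p <- length(g)
        ns <- design$scans_per_run[[s]]
        sd_s <- design$noise_sd[[s]]
        dk <- dark_profile(design, g)
        dark[[s]] <- dk + stats::rnorm(p, 0, sd_s)
        signal <- if (s == "FLUO") drift * latents[[s]] else
          drift * latents[[s]] * illum_profile(s, g)
        if (s != "FLUO")
          white[[s]] <- dk + illum_profile(s, g) + stats::rnorm(p, 0, sd_s)
        gain <- if (isTRUE(unname(saturate[s]))) design$sat_gain else 1
        m <- matrix(rep(dk + gain * signal, each = ns), nrow = ns) +
          stats::rnorm(ns * p, 0, sd_s)
        if (gain > 1) m <- pmin(m, design$sat_level)
        scans[[s]] <- m
      }
      measurement_run(sample_id, day, within_day, scans, dark, white, grids)
    })
}

replicate_coords <- function(k) {
  list(day = (k - 1L) %% 3L + 1L, within_day = (k - 1L) %/% 3L + 1L)
}

#' Generate the full synthetic study
#'
#' Oil library + admixtures + `n_replicates` measurement runs per sample.
#' Exactly `n_saturated_fluo` FLUO and `n_saturated_vis` VIS measurements
#' (chosen by a seeded draw over all runs) are over-exposed and clipped at
#' the detector ceiling so the saturation filter fires at measurement level.
#' Every run is reduced through [process_run()] (scan-level saturation
#' detection, averaging, dark/white correction, trimming to the used
#' window); with `keep_scans = TRUE` the raw [measurement_run()] objects are
#' retained as well (only advisable for small designs - the default design
#' generates ~296000 NIR scans).
#'
#' @param design a [study_design()].
#' @param keep_scans retain raw runs in the result.
#' @return list of class `oil_study`: `design`, `samples` (truth manifest,
#'   one row per sample), `latents`, `measurements` (per sensor: `X` matrix
#'   of corrected averaged spectra, `wavelengths`, `meta` with per-run
#'   `saturated` flag), `run_manifest` (per run: replicate coordinates and
#'   injected saturation), `counts` (samples, runs, scans per sensor), and
#'   optionally `runs`.
#' @export
generate_study <- function(design, keep_scans = FALSE) {
  lib <- generate_oil_library(design)
  adm <- generate_admixtures(lib, design)
  samples <- rbind(lib$samples, adm$samples)
  latents <- c(lib$latents, adm$latents)
  run_manifest <- expand.grid(k = seq_len(design$n_replicates),
                              sample_id = samples$sample_id,
                              stringsAsFactors = FALSE)[, 2:1]
  n_runs <- nrow(run_manifest)
  rc <- replicate_coords(run_manifest$k)
  run_manifest$day <- rc$day
  run_manifest$within_day <- rc$within_day
  run_manifest$sat_fluo <- run_manifest$sat_vis <- FALSE
  run_manifest$sat_fluo[withr::with_seed(
    derive_seed(design$seed, "satfluo"),
    sample(n_runs, design$n_saturated_fluo))] <- TRUE
  run_manifest$sat_vis[withr::with_seed(
    derive_seed(design$seed, "satvis"),
    sample(n_runs, design$n_saturated_vis))] <- TRUE

  sensors_used <- names(design$scans_per_run)
  used_grid <- lapply(design$sensors[sensors_used], function(sk)
    trim_grid(sensor_grid(sk), sk$used_range_nm))
  X <- lapply(sensors_used, function(s)
    matrix(NA_real_, n_runs, length(used_grid[[s]])))
  names(X) <- sensors_used
  sat_flag <- matrix(FALSE, n_runs, length(sensors_used),
                     dimnames = list(NULL, sensors_used))
  scan_counts <- stats::setNames(numeric(length(sensors_used)), sensors_used)
  runs <- if (keep_scans) vector("list", n_runs) else NULL
  for (i in seq_len(n_runs)) {
    rm_i <- run_manifest[i, ]
    run <- simulate_run(rm_i$sample_id, latents[[rm_i$sample_id]], rm_i$day,
                        rm_i$within_day, design,
                        saturate = c(FLUO = rm_i$sat_fluo,
                                     VIS = rm_i$sat_vis))
    if (keep_scans) runs[[i]] <- run
    pr <- process_run(run, design$sensors, sat_level = design$sat_level)
    for (s in names(pr)) {
      X[[s]][i, ] <- pr[[s]]$spectrum$intensities
      sat_flag[i, s] <- pr[[s]]$spectrum$saturated
      scan_counts[[s]] <- scan_counts[[s]] + pr[[s]]$n_scans
    }
  }
  measurements <- stats::setNames(lapply(sensors_used, function(s) list(
    X = X[[s]], wavelengths = used_grid[[s]],
    meta = data.frame(sample_id = run_manifest$sample_id,
                      day = run_manifest$day,
                      within_day = run_manifest$within_day,
                      saturated = sat_flag[, s],
                      stringsAsFactors = FALSE))), sensors_used)
  structure(list(design = design, samples = samples, latents = latents,
                 measurements = measurements, run_manifest = run_manifest,
                 counts = list(n_samples = nrow(samples), n_runs = n_runs,
                               scans = scan_counts),
                 runs = runs),
            class = "oil_study")
}

trim_grid <- function(grid, range) grid[grid >= range[1] & grid <= range[2]]

#' Drop saturated measurements from a study's measurement set
#'
#' Applies [filter_saturated()] semantics to the per-sensor measurement
#' matrices: flagged rows are removed and per-sensor removal counts
#' reported.
#'
#' @param study an `oil_study` from [generate_study()].
#' @return list with `measurements` (same shape, flagged rows removed) and
#'   `removed_counts` / `input_counts` per sensor.
#' @export
retained_measurements <- function(study) {
  out <- list(); removed <- input <- integer()
  for (s in names(study$measurements)) {
    m <- study$measurements[[s]]
    keep <- !m$meta$saturated
    out[[s]] <- list(X = m$X[keep, , drop = FALSE],
                     wavelengths = m$wavelengths,
                     meta = m$meta[keep, , drop = FALSE])
    removed[[s]] <- sum(!keep)
    input[[s]] <- nrow(m$X)
  }
  list(measurements = out, removed_counts = removed, input_counts = input)
}

#' @export
print.oil_study <- function(x, ...) {
  cat(sprintf("<oil_study> %d samples, %d runs; scans: %s\n",
              x$counts$n_samples, x$counts$n_runs,
              paste(sprintf("%s=%d", names(x$counts$scans),
                            as.integer(x$counts$scans)), collapse = " ")))
  invisible(x)
}
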