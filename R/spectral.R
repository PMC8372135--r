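#' Construct a measurement run
#'
#' One acquisition event for one sample replicate: all scans from all sensors
#' plus the dark references (every sensor) and white references (VIS/NIR only;
#' the fluorescence channel has no white standard). Scans of one sensor are
#' stored as a matrix (rows = scans) on that sensor's wavelength grid.
#'
#' @param sample_id sample identifier.
#' @param day measurement day (1-3).
#' @param within_day replicate index within the day (1-3).
#' @param scans named list, sensor name -> numeric matrix (scans x points).
#' @param dark named list, sensor name -> numeric vector (one dark spectrum).
#' @param white named list, sensor name -> numeric vector; must be absent
#'   (or `NULL`) for `FLUO`.
#' @param grids named list, sensor name -> wavelength grid (nm).
#' @return object of class `measurement_run`.
#' @export
measurement_run <- function(sample_id, day, within_day, scans, dark, white,
                            grids) {
  for (s in names(scans)) {
    p <- length(grids[[s]])
    if (ncol(scans[[s]]) != p || length(dark[[s]]) != p)
      stop_evoofuse(sprintf("grid mismatch for sensor %s", s), "grid_error")
    if (!is.null(white[[s]]) && length(white[[s]]) != p)
      stop_evoofuse(sprintf("white grid mismatch for sensor %s", s),
                    "grid_error")
  }
  if (!is.null(white[["FLUO"]]))
    stop_evoofuse("FLUO carries no white reference", "grid_error")
  structure(list(sample_id = sample_id, day = as.integer(day),
                 within_day = as.integer(within_day), scans = scans,
                 dark = dark, white = white, grids = grids),
            class = "measurement_run")
}

#' @export
print.measurement_run <- function(x, ...) {
  cat(sprintf("<measurement_run> %s day %d rep %d: %s\n", x$sample_id, x$day,
              x$within_day,
              paste(sprintf("%s x%d", names(x$scans),
                            vapply(x$scans, nrow, 0L)), collapse = ", ")))
  invisible(x)
}

#' Extract one scan of a run as a spectrum
#' @param run a `measurement_run`.
#' @param sensor sensor name.
#' @param i scan index.
#' @return a [spectrum()].
#' @export
run_scan <- function(run, sensor, i) {
  spectrum(sensor, run$grids[[sensor]], run$scans[[sensor]][i, ])
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && max(abs(a - b)) <= tol
}

#' Dark/white reference correction
#'
#' VIS and NIR transflectance scans are corrected for the dark current and
#' the 99% diffuse-reflectance white standard, giving relative reflectance
#' `(scan - dark) / (white - dark)`. Fluorescence scans are solely dark
#' corrected (`scan - dark`); there is no meaningful white standard for an
#' emission measurement, so passing one is an error.
#'
#' @param scan,dark [spectrum()] objects on a common wavelength grid.
#' @param white [spectrum()] for VIS/NIR; `NULL` (required) for FLUO.
#' @param eps positive floor below which `white - dark` is considered
#'   degenerate (dead reference pixel).
#' @return corrected [spectrum()] on the unchanged grid.
#' @export
reference_correct <- function(scan, dark, white = NULL, eps = 1e-9) {
  if (!same_grid(scan$wavelengths, dark$wavelengths))
    stop_evoofuse("scan and dark wavelength grids differ", "grid_error")
  is_fluo <- identical(scan$sensor, "FLUO")
  if (is_fluo) {
    if (!is.null(white))
      stop_evoofuse("FLUO correction takes no white reference", "grid_error")
    out <- scan$intensities - dark$intensities
  } else {
    if (is.null(white))
      stop_evoofuse("white reference required for VIS/NIR", "grid_error")
    if (!same_grid(scan$wavelengths, white$wavelengths))
      stop_evoofuse("scan and white wavelength grids differ", "grid_error")
    denom <- white$intensities - dark$intensities
    if (any(denom < eps))
      stop_evoofuse("degenerate white reference: white - dark below floor",
                    "degenerate_reference_error")
    out <- (scan$intensities - dark$intensities) / denom
  }
  spectrum(scan$sensor, scan$wavelengths, out, saturated = scan$saturated)
}

#' Trim a spectrum to a closed wavelength interval
#'
#' Detector edges carry irregular responses and are discarded before
#' modelling; both endpoints are retained (closed interval), so a 1 nm grid
#' over 939-1833 nm trimmed to 1020-1833 nm keeps 814 points.
#'
#' @param s a [spectrum()].
#' @param lo_nm,hi_nm interval bounds, `lo_nm < hi_nm`.
#' @return trimmed [spectrum()].
#' @export
trim_spectrum <- function(s, lo_nm, hi_nm) {
  stopifnot(lo_nm < hi_nm)
  keep <- s$wavelengths >= lo_nm & s$wavelengths <= hi_nm
  if (sum(keep) < 2L)
    stop_evoofuse("trim interval retains fewer than 2 points",
                  "empty_trim_error")
  spectrum(s$sensor, s$wavelengths[keep], s$intensities[keep],
           saturated = s$saturated)
}

#' Detect detector saturation in a scan
#'
#' Automated surrogate for visual outlier screening: a scan is saturated when
#' at least `min_run` consecutive intensities sit at or above the detector
#' ceiling `sat_level`. Requiring a run (default 3) ignores single-pixel
#' spikes.
#'
#' @param s a [spectrum()] or numeric intensity vector.
#' @param sat_level detector ceiling (counts), positive.
#' @param min_run minimum plateau length, >= 1.
#' @return logical.
#' @export
detect_saturation <- function(s, sat_level, min_run = 3L) {
  stopifnot(sat_level > 0, min_run >= 1L)
  x <- if (inherits(s, "spectrum")) s$intensities else as.numeric(s)
  r <- rle(x >= sat_level)
  any(r$values & r$lengths >= min_run)
}

#' Average the retained scans of one sensor in a run
#'
#' All scans acquired during one measurement run are averaged pointwise into
#' one spectrum per run. Scans flagged by `discard` (e.g. saturated ones) are
#' excluded; averaging nothing is an error and the measurement is dropped
#' downstream.
#'
#' @param run a [measurement_run()].
#' @param sensor sensor name.
#' @param discard optional logical vector, one element per scan.
#' @return a [spectrum()] on the sensor's grid.
#' @export
average_scans <- function(run, sensor, discard = NULL) {
  m <- run$scans[[sensor]]
  if (is.null(m) || nrow(m) == 0L)
    stop_evoofuse("no scans for sensor", "empty_measurement_error")
  if (!is.null(discard)) {
    stopifnot(length(discard) == nrow(m))
    m <- m[!discard, , drop = FALSE]
    if (nrow(m) == 0L)
      stop_evoofuse("all scans discarded", "empty_measurement_error")
  }
  spectrum(sensor, run$grids[[sensor]], colMeans(m))
}

#' Remove saturated measurements
#'
#' Drops every entry whose spectrum carries a saturation flag and reports how
#' many were removed per sensor; retained + removed always equals the input
#' size per sensor.
#'
#' @param measurements list of entries, each a list with elements
#'   `sample_id`, `sensor`, `spectrum` (a [spectrum()] with its `saturated`
#'   flag set).
#' @return list with `retained` (the surviving entries), `removed_counts`
#'   and `input_counts` (named integer vectors per sensor).
#' @export
filter_saturated <- function(measurements) {
  sensors <- vapply(measurements, function(e) e$sensor, "")
  flagged <- vapply(measurements, function(e) isTRUE(e$spectrum$saturated),
                    TRUE)
  input <- table(factor(sensors, levels = unique(sensors)))
  removed <- table(factor(sensors[flagged], levels = unique(sensors)))
  list(retained = measurements[!flagged],
       removed_counts = stats::setNames(as.integer(removed), names(removed)),
       input_counts = stats::setNames(as.integer(input), names(input)))
}

#' Reduce one measurement run to per-sensor corrected spectra
#'
#' Applies, per sensor: scan-level saturation detection, measurement-level
#' discarding when more than `sat_frac` of the scans are flagged (the whole
#' measurement is then marked saturated for that sensor), averaging of the
#' scans, dark/white reference correction, and trimming to the sensor's used
#' wavelength window.
#'
#' @param run a [measurement_run()].
#' @param sensors named list of `sensor_kind` (see [default_sensors()]).
#' @param sat_level detector ceiling in counts.
#' @param min_run plateau length for [detect_saturation()].
#' @param sat_frac fraction of flagged scans above which the measurement is
#'   discarded for that sensor.
#' @return named list per sensor: `spectrum` (corrected + trimmed
#'   [spectrum()], `saturated` flag set at measurement level) and `n_scans`.
#' @export
process_run <- function(run, sensors, sat_level = 65535, min_run = 3L,
                        sat_frac = 0.5) {
  out <- list()
  for (s in names(run$scans)) {
    m <- run$scans[[s]]
    flags <- apply(m, 1L, detect_saturation, sat_level = sat_level,
                   min_run = min_run)
    meas_sat <- mean(flags) > sat_frac
    keep <- if (meas_sat) rep(TRUE, nrow(m)) else !flags
    avg <- spectrum(s, run$grids[[s]], colMeans(m[keep, , drop = FALSE]),
                    saturated = meas_sat)
    dark <- spectrum(s, run$grids[[s]], run$dark[[s]])
    white <- if (is.null(run$white[[s]])) NULL else
      spectrum(s, run$grids[[s]], run$white[[s]])
    corr <- reference_correct(avg, dark, white)
    corr <- trim_spectrum(corr, sensors[[s]]$used_range_nm[1],
                          sensors[[s]]$used_range_nm[2])
    out[[s]] <- list(spectrum = corr, n_scans = nrow(m))
  }
  out
}
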