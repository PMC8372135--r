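#' @title Dataset file I/O
#' @description Long-format CSV serialization (UTF-8, '.' decimal) of raw
#'   measurement runs and of processed per-measurement spectra, plus a YAML
#'   design sidecar. Numeric values are written with 12 significant digits,
#'   so write-then-read reproduces a dataset to that precision.
#' @name dataset_io
NULL

known_sensors <- c("FLUO", "VIS", "NIR")

fmt_num <- function(x) sprintf("%.12g", x)

#' Write a raw dataset (samples + measurement runs) to a directory
#'
#' Writes `samples.csv` (the sample table), `spectra.csv` (long format: one
#' row per point of every scan, dark and white reference) and `design.yaml`
#' (scan-count / sensor sidecar).
#'
#' @param samples sample data frame (as in `oil_study$samples`).
#' @param runs list of [measurement_run()] objects.
#' @param path output directory (created if missing).
#' @param design optional [study_design()] for the sidecar.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(samples, runs, path, design = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(samples, file.path(path, "samples.csv"),
                   row.names = FALSE)
  blocks <- lapply(runs, function(run) {
    per_sensor <- lapply(names(run$scans), function(s) {
      g <- run$grids[[s]]
      m <- run$scans[[s]]
      scan_rows <- data.frame(
        sensor = s, role = "scan",
        scan = rep(seq_len(nrow(m)), each = length(g)),
        wavelength_nm = fmt_num(rep(g, nrow(m))),
        intensity = fmt_num(as.numeric(t(m))), stringsAsFactors = FALSE)
      ref_rows <- data.frame(
        sensor = s, role = "dark", scan = 0L, wavelength_nm = fmt_num(g),
        intensity = fmt_num(run$dark[[s]]), stringsAsFactors = FALSE)
      if (!is.null(run$white[[s]]))
        ref_rows <- rbind(ref_rows, data.frame(
          sensor = s, role = "white", scan = 0L, wavelength_nm = fmt_num(g),
          intensity = fmt_num(run$white[[s]]), stringsAsFactors = FALSE))
      rbind(ref_rows, scan_rows)
    })
    b <- do.call(rbind, per_sensor)
    cbind(data.frame(sample_id = run$sample_id, day = run$day,
                     within_day = run$within_day, stringsAsFactors = FALSE),
          b)
  })
  utils::write.csv(do.call(rbind, blocks), file.path(path, "spectra.csv"),
                   row.names = FALSE, quote = FALSE)
  sidecar <- list(sensors = lapply(known_sensors, function(s) {
    found <- Filter(function(r) s %in% names(r$scans), runs)
    if (!length(found)) return(NULL)
    list(name = s, n_points = length(found[[1]]$grids[[s]]))
  }))
  if (!is.null(design))
    sidecar$design <- design[c("n_replicates", "seed")]
  yaml::write_yaml(sidecar, file.path(path, "design.yaml"))
  invisible(path)
}

#' Read a raw dataset written by [write_dataset()]
#'
#' Validates the schema (required columns, known sensors, strictly ascending
#' wavelengths within every spectrum block) and reconstructs the sample
#' table and [measurement_run()] objects.
#'
#' @param path dataset directory.
#' @return list with `samples` and `runs`.
#' @export
read_dataset <- function(path) {
  samples <- utils::read.csv(file.path(path, "samples.csv"),
                             stringsAsFactors = FALSE)
  need_s <- c("sample_id", "oil_class")
  if (!all(need_s %in% names(samples)))
    stop_evoofuse(paste("samples.csv misses columns:",
                        paste(setdiff(need_s, names(samples)),
                              collapse = ", ")), "schema_error")
  sp <- utils::read.csv(file.path(path, "spectra.csv"),
                        stringsAsFactors = FALSE)
  need <- c("sample_id", "day", "within_day", "sensor", "role", "scan",
            "wavelength_nm", "intensity")
  if (!all(need %in% names(sp)))
    stop_evoofuse(paste("spectra.csv misses columns:",
                        paste(setdiff(need, names(sp)), collapse = ", ")),
                  "schema_error")
  bad <- which(!sp$sensor %in% known_sensors)
  if (length(bad))
    stop_evoofuse(sprintf("unknown sensor '%s' at spectra.csv row %d",
                          sp$sensor[bad[1]], bad[1]), "schema_error")
  sp$block <- paste(sp$sample_id, sp$day, sp$within_day, sp$sensor, sp$role,
                    sp$scan, sep = "\r")
  first_rows <- tapply(seq_len(nrow(sp)), sp$block, min)
  for (b in unique(sp$block)) {
    w <- sp$wavelength_nm[sp$block == b]
    if (any(diff(w) <= 0))
      stop_evoofuse(sprintf(
        "non-ascending wavelengths in block starting at spectra.csv row %d",
        first_rows[[b]]), "schema_error")
  }
  runs <- list()
  key_run <- unique(sp[, c("sample_id", "day", "within_day")])
  for (i in seq_len(nrow(key_run))) {
    sel <- sp$sample_id == key_run$sample_id[i] & sp$day == key_run$day[i] &
      sp$within_day == key_run$within_day[i]
    blk <- sp[sel, ]
    scans <- dark <- white <- grids <- list()
    for (s in unique(blk$sensor)) {
      bs <- blk[blk$sensor == s, ]
      dk <- bs[bs$role == "dark", ]
      grids[[s]] <- dk$wavelength_nm
      dark[[s]] <- dk$intensity
      wh <- bs[bs$role == "white", ]
      if (nrow(wh)) white[[s]] <- wh$intensity
      sc <- bs[bs$role == "scan", ]
      idx <- sort(unique(sc$scan))
      scans[[s]] <- do.call(rbind, lapply(idx, function(k)
        sc$intensity[sc$scan == k]))
    }
    runs[[i]] <- measurement_run(key_run$sample_id[i], key_run$day[i],
                                 key_run$within_day[i], scans, dark, white,
                                 grids)
  }
  list(samples = samples, runs = runs)
}

#' Write / read processed per-measurement spectra
#'
#' Long CSV of the corrected, trimmed, averaged per-measurement spectra that
#' all downstream modules consume (one row per wavelength per measurement per
#' sensor, with the measurement-level saturation flag).
#'
#' @param measurements per-sensor measurement set (as in
#'   `oil_study$measurements`).
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_measurements_csv <- function(measurements, file) {
  blocks <- lapply(names(measurements), function(s) {
    m <- measurements[[s]]
    p <- length(m$wavelengths)
    data.frame(sample_id = rep(m$meta$sample_id, each = p),
               day = rep(m$meta$day, each = p),
               within_day = rep(m$meta$within_day, each = p),
               sensor = s, saturated = rep(m$meta$saturated, each = p),
               wavelength_nm = fmt_num(rep(m$wavelengths, nrow(m$X))),
               intensity = fmt_num(as.numeric(t(m$X))),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, blocks), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' @rdname write_measurements_csv
#' @param file CSV path to read.
#' @return `read_measurements_csv` returns the per-sensor measurement set.
#' @export
read_measurements_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "day", "within_day", "sensor", "saturated",
            "wavelength_nm", "intensity")
  if (!all(need %in% names(d)))
    stop_evoofuse(paste("measurements CSV misses columns:",
                        paste(setdiff(need, names(d)), collapse = ", ")),
                  "schema_error")
  out <- list()
  for (s in unique(d$sensor)) {
    ds <- d[d$sensor == s, ]
    w <- unique(ds$wavelength_nm)
    key <- paste(ds$sample_id, ds$day, ds$within_day, sep = "\r")
    ukey <- unique(key)
    X <- matrix(ds$intensity, nrow = length(ukey), byrow = TRUE)
    meta_rows <- match(ukey, key)
    out[[s]] <- list(X = X, wavelengths = w,
                     meta = data.frame(sample_id = ds$sample_id[meta_rows],
                                       day = ds$day[meta_rows],
                                       within_day = ds$within_day[meta_rows],
                                       saturated = ds$saturated[meta_rows],
                                       stringsAsFactors = FALSE))
  }
  out
}
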