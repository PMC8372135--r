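#' Sensor definitions and the spectrum container
#'
#' The pipeline handles three co-registered optical channels measured in
#' transflectance geometry on the same sample spot: fluorescence (FLUO,
#' 365 nm excitation, read out on the UV-Vis detector), diffuse-reflectance
#' visible (VIS, same detector), and near-infrared (NIR, MEMS spectrometer).
#' A `sensor_kind` records the raw detector grid and the wavelength window
#' actually used for modelling (detector edges are noisy and are discarded).
#'
#' @param name one of `"FLUO"`, `"VIS"`, `"NIR"`.
#' @param raw_range_nm length-2 numeric, closed raw wavelength interval.
#' @param raw_n_points number of detector pixels across the raw range.
#' @param used_range_nm length-2 numeric, closed interval retained for
#'   modelling; must lie inside `raw_range_nm`.
#' @return an object of class `sensor_kind`.
#' @export
sensor_kind <- function(name, raw_range_nm, raw_n_points, used_range_nm) {
  name <- match.arg(name, c("FLUO", "VIS", "NIR"))
  stopifnot(length(raw_range_nm) == 2L, raw_range_nm[1] < raw_range_nm[2],
            raw_n_points >= 2L, length(used_range_nm) == 2L,
            used_range_nm[1] < used_range_nm[2])
  if (used_range_nm[1] < raw_range_nm[1] || used_range_nm[2] > raw_range_nm[2])
    stop_evoofuse("used_range_nm must lie inside raw_range_nm", "sensor_error")
  structure(list(name = name,
                 raw_range_nm = as.numeric(raw_range_nm),
                 raw_n_points = as.integer(raw_n_points),
                 used_range_nm = as.numeric(used_range_nm)),
            class = "sensor_kind")
}

#' Default sensor set
#'
#' NIR: 939-1833 nm on 895 pixels (exactly 1 nm spacing), 1020-1833 nm used.
#' VIS and FLUO share one detector spanning 320-889 nm on 288 pixels; the
#' VIS channel uses 400-740 nm and the FLUO channel 340-780 nm. The shared
#' detector grid is taken uniform here; the physical instrument has a
#' nonlinear pixel-to-wavelength calibration that is not modelled.
#'
#' @param nir_n_points,uvvis_n_points detector pixel counts, overridable for
#'   fast reduced-resolution simulations.
#' @return named list of `sensor_kind` objects (`FLUO`, `VIS`, `NIR`).
#' @export
default_sensors <- function(nir_n_points = 895L, uvvis_n_points = 288L) {
  list(
    FLUO = sensor_kind("FLUO", c(320, 889), uvvis_n_points, c(340, 780)),
    VIS  = sensor_kind("VIS",  c(320, 889), uvvis_n_points, c(400, 740)),
    NIR  = sensor_kind("NIR",  c(939, 1833), nir_n_points, c(1020, 1833))
  )
}

#' Raw wavelength grid of a sensor
#' @param sensor a `sensor_kind`.
#' @return numeric vector of length `raw_n_points`, strictly ascending.
#' @export
sensor_grid <- function(sensor) {
  seq(sensor$raw_range_nm[1], sensor$raw_range_nm[2],
      length.out = sensor$raw_n_points)
}

#' Construct a spectrum
#'
#' A single wavelength-indexed intensity trace from one sensor, in detector
#' counts (raw, dark) or relative reflectance (corrected), with a saturation
#' flag set by [detect_saturation()].
#'
#' @param sensor sensor name (`"FLUO"`, `"VIS"`, `"NIR"`) or a `sensor_kind`.
#' @param wavelengths strictly ascending numeric vector (nm).
#' @param intensities numeric vector, same length as `wavelengths`.
#' @param saturated logical flag.
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(sensor, wavelengths, intensities, saturated = FALSE) {
  if (inherits(sensor, "sensor_kind")) sensor <- sensor$name
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) < 2L || length(wavelengths) != length(intensities))
    stop_evoofuse("need >= 2 points and equal-length wavelength/intensity",
                  "spectrum_error")
  if (any(diff(wavelengths) <= 0))
    stop_evoofuse("wavelengths must be strictly ascending", "spectrum_error")
  structure(list(sensor = sensor, wavelengths = wavelengths,
                 intensities = intensities, saturated = isTRUE(saturated)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %d points, %.1f-%.1f nm%s\n", x$sensor,
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              if (x$saturated) ", SATURATED" else ""))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$wavelengths)
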