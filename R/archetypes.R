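#' Gaussian band model
#'
#' Spectral features are modelled as Gaussian bands in wavelength. Real
#' pigment bands are asymmetric, but the band shape is irrelevant to the
#' pipeline logic and Gaussians keep the test oracles analytic.
#'
#' @param center_nm band center (nm).
#' @param width_nm Gaussian width parameter (nm), positive.
#' @param amplitude peak amplitude, nonnegative.
#' @return list of class `band_model`.
#' @export
band_model <- function(center_nm, width_nm, amplitude) {
  stopifnot(width_nm > 0, amplitude >= 0)
  structure(list(center_nm = center_nm, width_nm = width_nm,
                 amplitude = amplitude), class = "band_model")
}

# evaluate a list of bands on a wavelength grid, with optional per-band
# amplitude factors
eval_bands <- function(bands, grid, factors = rep(1, length(bands))) {
  out <- numeric(length(grid))
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    out <- out + factors[i] * b$amplitude *
      exp(-((grid - b$center_nm) / b$width_nm)^2)
  }
  out
}

#' Oil class archetypes
#'
#' Latent spectral archetypes for the four oil classes, built around the
#' pheophytin-a pigment signature of virgin olive oil:
#' * FLUO (emission, detector counts under 365 nm excitation): a phenolic /
#'   carotenoid band at 350-400 nm, the Soret band at 400-500 nm and the
#'   dominant q-band at 650-690 nm. EVOO has the strongest q-band; refining
#'   (RVOO) and pomace processing (OPO) degrade the porphyrins by 70-80%;
#'   non-olive seed oils have almost no q-band (<= 5% of EVOO's) but retain
#'   some 350-400 nm fluorescence.
#' * VIS (relative transflectance): pigment absorption carves Soret- and
#'   q-band dips into a smooth high-reflectance baseline; refined oils are
#'   nearly translucent.
#' * NIR (relative transflectance): all edible oils share the same C-H/
#'   triglyceride overtone bands; classes differ only by small coefficients
#'   on those shared bands, so NIR carries deliberately weak class
#'   information.
#'
#' `between_sample_cv` is the lognormal coefficient of variation applied per
#' band when sampling individual oils: EVOO is comparatively uniform, the
#' other classes heterogeneous.
#'
#' @return named list (per class `EVOO`, `RVOO`, `OPO`, `OTHER`) of
#'   archetypes with elements `fluo_bands`, `vis_bands`, `nir_band_scale`,
#'   `between_sample_cv`, `nir_cv`.
#' @export
oil_archetypes <- function() {
  fluo <- function(phenol, soret, q, shoulder) list(
    band_model(375, 18, phenol), band_model(455, 22, soret),
    band_model(672, 11, q), band_model(720, 16, shoulder))
  vis <- function(scale) list(
    band_model(420, 15, 0.45 * scale), band_model(455, 18, 0.30 * scale),
    band_model(480, 25, 0.15 * scale), band_model(612, 10, 0.08 * scale),
    band_model(670, 10, 0.35 * scale))
  list(
    EVOO  = list(fluo_bands = fluo(9000, 14000, 32000, 4000),
                 vis_bands = vis(1.00), nir_band_scale = 1.000,
                 between_sample_cv = 0.08, nir_cv = 0.03),
    RVOO  = list(fluo_bands = fluo(5000, 4500, 9000, 1200),
                 vis_bands = vis(0.30), nir_band_scale = 1.020,
                 between_sample_cv = 0.30, nir_cv = 0.03),
    OPO   = list(fluo_bands = fluo(3500, 3000, 6000, 800),
                 vis_bands = vis(0.20), nir_band_scale = 1.035,
                 between_sample_cv = 0.35, nir_cv = 0.03),
    OTHER = list(fluo_bands = fluo(7000, 900, 1200, 200),
                 vis_bands = vis(0.04), nir_band_scale = 0.970,
                 between_sample_cv = 0.40, nir_cv = 0.03)
  )
}

# shared NIR macro-composition bands (C-H first/second overtones and
# combination bands of triglycerides) as absorption dips in transflectance
nir_shared_bands <- function() list(
  band_model(1210, 25, 0.12), band_model(1400, 40, 0.18),
  band_model(1725, 20, 0.28), band_model(1760, 18, 0.22))

# lognormal multiplicative factors with mean 1 and coefficient of variation
# `cv` (cv = 0 returns exactly 1)
lognorm_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sdlog) - sdlog^2 / 2)
}

# draw one oil's latent noiseless spectra (per sensor, on the raw grids)
draw_latents <- function(class, design) {
  at <- design$archetypes[[class]]
  cv <- at$between_sample_cv * design$cv_scale
  g <- lapply(design$sensors, sensor_grid)
  f_fluo <- lognorm_factors(length(at$fluo_bands), cv)
  f_vis <- lognorm_factors(length(at$vis_bands), cv)
  f_nir <- at$nir_band_scale *
    lognorm_factors(length(nir_shared_bands()), at$nir_cv * design$cv_scale)
  list(
    FLUO = eval_bands(at$fluo_bands, g$FLUO, f_fluo),
    VIS = pmax(design$vis_baseline - eval_bands(at$vis_bands, g$VIS, f_vis),
               0.02),
    NIR = pmax(design$nir_baseline -
                 eval_bands(nir_shared_bands(), g$NIR, f_nir), 0.02)
  )
}
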