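# shared fixtures: reduced-resolution sensors and a small study design so a
# full study generates in well under a second

small_sensors <- function() {
  default_sensors(nir_n_points = 113L, uvvis_n_points = 96L)
}

small_design <- function(seed = 7L, ...) {
  args <- list(n_evoo = 8L, n_rvoo = 5L, n_opo = 3L, n_other = 5L,
               n_mix_olive = 4L, n_mix_other = 6L, n_replicates = 3L,
               scans_per_run = c(VIS = 3L, FLUO = 3L, NIR = 5L),
               n_saturated_fluo = 4L, n_saturated_vis = 3L,
               sensors = small_sensors(), seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(study_design, args)
}

# memoise the small study: several test files reuse it read-only
.fixture_env <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- generate_study(small_design())
  .fixture_env$study
}

rand_spectrum <- function(n = 20L, sensor = "VIS", seed = 1L) {
  withr::with_seed(seed,
    spectrum(sensor, seq(400, 700, length.out = n), runif(n, 10, 100)))
}
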