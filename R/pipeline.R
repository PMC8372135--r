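#' @title End-to-end pipeline and file-based stages
#' @description High-level orchestration of the full authentication study:
#'   generate (or load) the measurements, rank the model grid over repeated
#'   grouped splits, select models by per-sensor quota, score all samples
#'   with the selected models (EVOO samples out-of-fold), tune the two
#'   threshold scenarios, fuse votes and tabulate rates. The `stage_*`
#'   functions are the file-based equivalents wrapped by the command-line
#'   interface.
#' @name pipeline
NULL

#' Score all samples with one selected model
#'
#' Fits the model spec on all pure-EVOO measurements and scores every
#' non-EVOO measurement with it; pure-EVOO measurements are scored
#' out-of-fold under a grouped 5-fold split (all measurements of one EVOO
#' sample leave together), so no EVOO sample is scored by a model that saw
#' it. Hyperparameters come from grouped inner cross-validation on the EVOO
#' measurements. Per-measurement distances are averaged into per-sample
#' distances.
#'
#' @param m one sensor's measurement set (`X`, `wavelengths`, `meta`).
#' @param samples sample table with `truth_class`.
#' @param algorithm,spec algorithm name and [preprocess_spec()].
#' @param seed seed for fold assignment.
#' @param n_folds folds for the out-of-fold EVOO scoring.
#' @return named per-sample distance vector (all samples with measurements).
#' @export
score_selected_model <- function(m, samples, algorithm, spec, seed = 1L,
                                 n_folds = 5L) {
  Fm <- apply_preprocess(spec, m$X, m$wavelengths)
  truth <- stats::setNames(samples$truth_class, samples$sample_id)
  is_evoo_row <- truth[m$meta$sample_id] == "EVOO"
  evoo_ids <- unique(m$meta$sample_id[is_evoo_row])
  X_evoo <- Fm[is_evoo_row, , drop = FALSE]
  ids_evoo <- m$meta$sample_id[is_evoo_row]
  hyper <- inner_cv_select(algorithm, X_evoo, ids_evoo,
                           seed = derive_seed(seed, "cv"))
  model_full <- occ_fit(algorithm, X_evoo, hyper)
  d <- numeric(nrow(Fm))
  d[!is_evoo_row] <- occ_distance(model_full,
                                  Fm[!is_evoo_row, , drop = FALSE])
  fold_of <- withr::with_seed(derive_seed(seed, "oof"),
    stats::setNames(sample(rep_len(seq_len(n_folds), length(evoo_ids))),
                    evoo_ids))
  for (f in seq_len(n_folds)) {
    in_fold <- is_evoo_row & fold_of[m$meta$sample_id] == f
    tr <- is_evoo_row & !in_fold
    mod <- occ_fit(algorithm, Fm[tr, , drop = FALSE], hyper)
    d[in_fold] <- occ_distance(mod, Fm[in_fold, , drop = FALSE])
  }
  aggregate_sample_distance(d, m$meta$sample_id)
}

parse_model_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  list(sensor = parts[1], algorithm = parts[2],
       grid_key = paste(parts[-1], collapse = "|"))
}

#' Per-sample distance matrix of the selected models
#'
#' @param meas per-sensor measurement set (saturation-filtered).
#' @param samples sample table with `truth_class`.
#' @param grid model grid from [enumerate_model_grid()].
#' @param selected selected model keys (`SENSOR|ALGORITHM|preprocess`).
#' @param seed root seed.
#' @return matrix, rows = samples, columns = selected model keys.
#' @export
selected_model_distances <- function(meas, samples, grid, selected,
                                     seed = 1L) {
  cols <- lapply(selected, function(key) {
    pk <- parse_model_key(key)
    g <- grid[grid$key == pk$grid_key, ]
    if (!nrow(g))
      stop_evoofuse(paste("selected key not in grid:", key),
                    "selection_error")
    score_selected_model(meas[[pk$sensor]], samples, g$algorithm[1],
                         g$preprocess[[1]],
                         seed = derive_seed(seed, "final", key))
  })
  ids <- sort(unique(unlist(lapply(cols, names))))
  out <- matrix(NA_real_, length(ids), length(selected),
                dimnames = list(ids, selected))
  for (j in seq_along(cols)) out[names(cols[[j]]), j] <- cols[[j]]
  # a sample can lose all measurements of one sensor to saturation
  dropped <- rownames(out)[!stats::complete.cases(out)]
  if (length(dropped)) {
    warning("dropping samples without retained measurements on every ",
            "selected sensor: ", paste(dropped, collapse = ", "))
    out <- out[stats::complete.cases(out), , drop = FALSE]
  }
  out
}

#' Run the complete authentication study in memory
#'
#' @param design a [study_design()].
#' @param grid model grid (default [enumerate_model_grid()]; reduce for
#'   speed).
#' @param quotas per-sensor selection quotas.
#' @param n_repeats outer split repeats for ranking.
#' @param min_votes fused vote minimum.
#' @param evoo_rate_floor scenario-2 EVOO-rate floor.
#' @param seed root seed (defaults to the design's).
#' @return list with the study, ranking results, `selected` keys, the
#'   per-sample `distances` matrix, per-scenario `thresholds`, `decisions`,
#'   `rate_tables` and `detection` curves.
#' @export
run_authentication_study <- function(design, grid = enumerate_model_grid(),
                                     quotas = c(FLUO = 6L, VIS = 2L,
                                                NIR = 2L),
                                     n_repeats = 5L, min_votes = 2L,
                                     evoo_rate_floor = 0.75, seed = NULL) {
  seed <- seed %||% design$seed
  study <- generate_study(design)
  ret <- retained_measurements(study)
  rank <- rank_model_grid(ret$measurements, study$samples, grid,
                          n_repeats = n_repeats, seed = seed)
  selected <- rank_and_select(rank$performance, quotas)
  dist <- selected_model_distances(ret$measurements, study$samples, grid,
                                   selected, seed = seed)
  truth <- stats::setNames(study$samples$truth_class,
                           study$samples$sample_id)
  scen <- list(
    S1 = scenario_config("S1_NO_FALSE_NEGATIVE", min_votes = min_votes),
    S2 = scenario_config("S2_FRAUD_SCREEN", min_votes = min_votes,
                         evoo_rate_floor = evoo_rate_floor))
  thresholds <- lapply(scen, function(cf) tune_thresholds(dist, truth, cf))
  decisions <- lapply(thresholds, function(th)
    decide_samples(dist, th, min_votes))
  rate_tables <- lapply(thresholds, function(th)
    rate_table(dist, th, truth, min_votes))
  detection <- lapply(decisions, function(dec)
    detection_by_fraction(dec, study$samples))
  list(study = study, ranking = rank, selected = selected, distances = dist,
       thresholds = thresholds, decisions = decisions,
       rate_tables = rate_tables, detection = detection,
       retained = ret)
}

#' Fit the selected models on all pure-EVOO measurements
#'
#' Deployment counterpart of [selected_model_distances()]: each selected
#' (sensor, preprocessing, algorithm) combination is tuned by grouped inner
#' cross-validation and fitted once on every retained pure-EVOO measurement,
#' yielding a model bank that can score new, unseen samples.
#'
#' @inheritParams selected_model_distances
#' @return list of fitted entries (`key`, `sensor`, `algorithm`, `spec`,
#'   `model`), of class `occ_model_bank`.
#' @export
fit_selected_models <- function(meas, samples, grid, selected, seed = 1L) {
  truth <- stats::setNames(samples$truth_class, samples$sample_id)
  bank <- lapply(selected, function(key) {
    pk <- parse_model_key(key)
    g <- grid[grid$key == pk$grid_key, ]
    if (!nrow(g))
      stop_evoofuse(paste("selected key not in grid:", key),
                    "selection_error")
    m <- meas[[pk$sensor]]
    Fm <- apply_preprocess(g$preprocess[[1]], m$X, m$wavelengths)
    evoo_rows <- truth[m$meta$sample_id] == "EVOO"
    ids <- m$meta$sample_id[evoo_rows]
    hyper <- inner_cv_select(g$algorithm[1], Fm[evoo_rows, , drop = FALSE],
                             ids, seed = derive_seed(seed, "bank", key))
    list(key = key, sensor = pk$sensor, algorithm = g$algorithm[1],
         spec = g$preprocess[[1]],
         model = occ_fit(g$algorithm[1], Fm[evoo_rows, , drop = FALSE],
                         hyper))
  })
  structure(bank, class = "occ_model_bank")
}

#' Score new measurements with a fitted model bank
#'
#' @param bank an `occ_model_bank` from [fit_selected_models()].
#' @param meas per-sensor measurement set of the new samples.
#' @return per-sample distance matrix (rows = samples, columns = model keys).
#' @export
predict_sample_distances <- function(bank, meas) {
  cols <- lapply(bank, function(b) {
    m <- meas[[b$sensor]]
    Fm <- apply_preprocess(b$spec, m$X, m$wavelengths)
    aggregate_sample_distance(occ_distance(b$model, Fm), m$meta$sample_id)
  })
  ids <- sort(unique(unlist(lapply(cols, names))))
  out <- matrix(NA_real_, length(ids), length(bank),
                dimnames = list(ids, vapply(bank, `[[`, "", "key")))
  for (j in seq_along(cols)) out[names(cols[[j]]), j] <- cols[[j]]
  out
}

# ---- file-based stages (wrapped by the CLI) --------------------------------

#' Default pipeline configuration
#'
#' @return nested list mirroring the YAML config consumed by the CLI:
#'   `design` (arguments of [study_design()]), `grid` (arguments of
#'   [enumerate_model_grid()]; `splits` uses `"full"` for the unsplit
#'   spectrum), `quotas`, `n_repeats`, `min_votes`, `evoo_rate_floor`,
#'   `scenario`, `seed`.
#' @export
default_config <- function() {
  list(design = list(), seed = 1L,
       grid = list(preprocess = list("snv", "snv_detrend", "sg1", "sg2",
                                     "dwt_haar", "dwt_la8"),
                   splits = list("full", 1L, 2L, 3L, 4L),
                   algorithms = list("SIMCA", "KNN", "PCA_RESIDUAL",
                                     "MAHALANOBIS", "OCSVM_RBF")),
       quotas = list(FLUO = 6L, VIS = 2L, NIR = 2L),
       n_repeats = 5L, min_votes = 2L, evoo_rate_floor = 0.75,
       scenario = 1L)
}

config_design <- function(config) {
  d <- config$design %||% list()
  # YAML carries named lists; study_design wants atomic vectors
  for (f in c("scans_per_run", "noise_sd", "mix_levels"))
    if (!is.null(d[[f]])) d[[f]] <- unlist(d[[f]])
  if (!is.null(d$sensors) && !inherits(d$sensors[[1]], "sensor_kind"))
    d$sensors <- do.call(default_sensors, lapply(d$sensors, as.integer))
  do.call(study_design, c(d, list(seed = config$seed %||% 1L)))
}

config_grid <- function(config) {
  g <- config$grid %||% default_config()$grid
  splits <- vapply(g$splits, function(s)
    if (identical(s, "full")) NA_real_ else as.numeric(s), 0)
  enumerate_model_grid(preprocess = g$preprocess, splits = splits,
                       algorithms = unlist(g$algorithms))
}

need_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop_evoofuse(sprintf("missing artifact '%s'; run `%s` first", path,
                          produced_by), "data_error")
  path
}

stage_log <- function(outdir, stage, info) {
  log <- file.path(outdir, sprintf("log_%s.yaml", stage))
  yaml::write_yaml(c(list(stage = stage, time = format(Sys.time())), info),
                   log)
}

#' Pipeline stages operating on files
#'
#' Each stage reads the previous stage's artifacts from `outdir`, writes its
#' own documented outputs plus a structured YAML log, and is wrapped 1:1 by
#' the `evoofuse` command-line interface (`simulate`, `train`, `select`,
#' `tune`, `decide`, `evaluate`, `report`).
#'
#' @param config configuration list (see [default_config()]).
#' @param outdir working directory for the artifacts.
#' @return each stage returns its main result invisibly.
#' @export
stage_simulate <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  design <- config_design(config)
  study <- generate_study(design)
  utils::write.csv(study$samples, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(study$run_manifest, file.path(outdir, "run_manifest.csv"),
                   row.names = FALSE)
  write_measurements_csv(study$measurements,
                         file.path(outdir, "measurements.csv"))
  stage_log(outdir, "simulate",
            list(seed = design$seed, n_samples = study$counts$n_samples,
                 n_runs = study$counts$n_runs,
                 scans = as.list(study$counts$scans)))
  invisible(study)
}

read_stage_inputs <- function(outdir) {
  samples <- utils::read.csv(need_artifact(file.path(outdir, "manifest.csv"),
                                           "simulate"),
                             stringsAsFactors = FALSE)
  meas <- read_measurements_csv(need_artifact(
    file.path(outdir, "measurements.csv"), "simulate"))
  keep <- lapply(meas, function(m) {
    k <- !m$meta$saturated
    list(X = m$X[k, , drop = FALSE], wavelengths = m$wavelengths,
         meta = m$meta[k, , drop = FALSE])
  })
  list(samples = samples, measurements = keep)
}

#' @rdname stage_simulate
#' @export
stage_train <- function(config, outdir) {
  inp <- read_stage_inputs(outdir)
  grid <- config_grid(config)
  rank <- rank_model_grid(inp$measurements, inp$samples, grid,
                          n_repeats = config$n_repeats %||% 5L,
                          seed = config$seed %||% 1L)
  utils::write.csv(rank$performance, file.path(outdir, "performance.csv"),
                   row.names = FALSE)
  stage_log(outdir, "train", list(n_models = nrow(rank$performance),
                                  n_repeats = config$n_repeats %||% 5L))
  invisible(rank)
}

#' @rdname stage_simulate
#' @export
stage_select <- function(config, outdir) {
  perf <- utils::read.csv(need_artifact(file.path(outdir, "performance.csv"),
                                        "train"), stringsAsFactors = FALSE)
  quotas <- unlist(config$quotas %||% default_config()$quotas)
  selected <- rank_and_select(perf, quotas)
  yaml::write_yaml(list(selected = as.list(selected)),
                   file.path(outdir, "selection.yaml"))
  stage_log(outdir, "select", list(n_selected = length(selected)))
  invisible(selected)
}

#' @rdname stage_simulate
#' @export
stage_tune <- function(config, outdir) {
  inp <- read_stage_inputs(outdir)
  selected <- unlist(yaml::read_yaml(need_artifact(
    file.path(outdir, "selection.yaml"), "select"))$selected)
  grid <- config_grid(config)
  dist <- selected_model_distances(inp$measurements, inp$samples, grid,
                                   selected, seed = config$seed %||% 1L)
  utils::write.csv(data.frame(sample_id = rownames(dist), dist,
                              check.names = FALSE),
                   file.path(outdir, "final_distances.csv"),
                   row.names = FALSE)
  truth <- stats::setNames(inp$samples$truth_class, inp$samples$sample_id)
  cf <- if ((config$scenario %||% 1L) == 1L)
    scenario_config("S1_NO_FALSE_NEGATIVE",
                    min_votes = config$min_votes %||% 2L)
  else
    scenario_config("S2_FRAUD_SCREEN", min_votes = config$min_votes %||% 2L,
                    evoo_rate_floor = config$evoo_rate_floor %||% 0.75)
  th <- tune_thresholds(dist, truth, cf)
  yaml::write_yaml(list(scenario = cf$scenario,
                        min_votes = cf$min_votes,
                        quantile = attr(th, "quantile"),
                        thresholds = as.list(stats::setNames(as.numeric(th),
                                                             names(th)))),
                   file.path(outdir, "thresholds.yaml"))
  stage_log(outdir, "tune", list(scenario = cf$scenario))
  invisible(th)
}

read_final_distances <- function(outdir) {
  d <- utils::read.csv(need_artifact(file.path(outdir,
                                               "final_distances.csv"),
                                     "tune"),
                       stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$sample_id
  m
}

#' @rdname stage_simulate
#' @export
stage_decide <- function(config, outdir) {
  dist <- read_final_distances(outdir)
  ty <- yaml::read_yaml(need_artifact(file.path(outdir, "thresholds.yaml"),
                                      "tune"))
  th <- unlist(ty$thresholds)
  dec <- decide_samples(dist, th, ty$min_votes)
  samples <- utils::read.csv(file.path(outdir, "manifest.csv"),
                             stringsAsFactors = FALSE)
  dec$truth_class <- samples$truth_class[match(dec$sample_id,
                                               samples$sample_id)]
  utils::write.csv(dec, file.path(outdir, "decisions.csv"),
                   row.names = FALSE)
  stage_log(outdir, "decide",
            list(n_flagged = sum(dec$flag == "NON_EVOO")))
  invisible(dec)
}

#' @rdname stage_simulate
#' @export
stage_evaluate <- function(config, outdir) {
  dist <- read_final_distances(outdir)
  ty <- yaml::read_yaml(need_artifact(file.path(outdir, "thresholds.yaml"),
                                      "tune"))
  samples <- utils::read.csv(need_artifact(file.path(outdir, "manifest.csv"),
                                           "simulate"),
                             stringsAsFactors = FALSE)
  truth <- stats::setNames(samples$truth_class, samples$sample_id)
  rt <- rate_table(dist, unlist(ty$thresholds), truth, ty$min_votes)
  utils::write.csv(rt, file.path(outdir, "rate_table.csv"),
                   row.names = FALSE)
  dec <- utils::read.csv(need_artifact(file.path(outdir, "decisions.csv"),
                                       "decide"), stringsAsFactors = FALSE)
  det <- detection_by_fraction(dec, samples)
  utils::write.csv(det, file.path(outdir, "detection.csv"),
                   row.names = FALSE)
  stage_log(outdir, "evaluate", list(classes = rt$class))
  invisible(list(rate_table = rt, detection = det))
}

#' @rdname stage_simulate
#' @export
stage_report <- function(config, outdir) {
  rt <- utils::read.csv(need_artifact(file.path(outdir, "rate_table.csv"),
                                      "evaluate"), stringsAsFactors = FALSE,
                        check.names = FALSE)
  cell <- function(col, i) if (col %in% names(rt)) rt[[col]][i] else NA
  md <- c("| Sample | n | fused % | FLUO % | NIR % | VIS % |",
          "|---|---|---|---|---|---|",
          vapply(seq_len(nrow(rt)), function(i)
            sprintf("| %s | %d | %s | %s | %s | %s |", rt$class[i], rt$n[i],
                    rt$fused[i], cell("FLUO", i), cell("NIR", i),
                    cell("VIS", i)), ""))
  md <- c("# Correct classification rates", "", md)
  writeLines(md, file.path(outdir, "rate_table.md"))
  stage_log(outdir, "report", list(rows = nrow(rt)))
  invisible(rt)
}
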