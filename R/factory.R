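#' @title Model factory: grouped splitting, AUROC ranking, quota selection
#' @description Orchestrates model generation and selection: the EVOO samples
#'   are split at the sample level (all nine measurements of a sample stay
#'   together), the full preprocessing x algorithm grid is trained per sensor
#'   on the training EVOOs, held-out EVOOs and all non-EVOO samples are
#'   scored and averaged per sample, each model is ranked by its AUROC
#'   against three adversary groups (lower-quality olive oils, other edible
#'   oils, adulterated EVOOs), and a per-sensor quota of top models is
#'   selected.
#' @name model_factory
NULL

#' Grouped train/test split of EVOO samples
#'
#' Draws `floor(fraction * n)` EVOO samples into the training side without
#' replacement; all measurements of one sample fall wholly on one side.
#'
#' @param evoo_sample_ids character vector of distinct EVOO sample ids.
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed for the draw.
#' @return list with `train_sample_ids`, `test_sample_ids`, `fraction`.
#' @export
grouped_split <- function(evoo_sample_ids, fraction = 0.8, seed = 1L) {
  ids <- unique(evoo_sample_ids)
  n <- length(ids)
  if (n < 2L) stop_evoofuse("need >= 2 EVOO samples to split", "split_error")
  n_train <- floor(fraction * n)
  if (n_train < 1L || n_train >= n)
    stop_evoofuse("split leaves train or test empty", "split_error")
  train <- withr::with_seed(seed, sample(ids, n_train))
  list(train_sample_ids = sort(train),
       test_sample_ids = sort(setdiff(ids, train)),
       fraction = fraction)
}

#' Average per-measurement class distances into one per-sample distance
#'
#' @param distances numeric vector of per-measurement class distances.
#' @param sample_ids sample id of each measurement.
#' @return named numeric vector, mean distance per sample.
#' @export
aggregate_sample_distance <- function(distances, sample_ids) {
  if (!length(distances))
    stop_evoofuse("no measurements to aggregate", "input_error")
  res <- tapply(distances, sample_ids, mean)
  stats::setNames(as.vector(res), names(res))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `P(adversary > target) + 0.5 * P(tie)` over all pairs: the probability
#' that an out-of-class sample's class distance exceeds an EVOO's, computed
#' from joint ranks.
#'
#' @param target_distances class distances of the target (EVOO) samples.
#' @param adversary_distances class distances of the adversary samples.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(target_distances, adversary_distances) {
  t <- as.numeric(target_distances); a <- as.numeric(adversary_distances)
  if (!length(t) || !length(a))
    stop_evoofuse("both distance lists must be nonempty", "input_error")
  r <- rank(c(a, t))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  u / (length(a) * length(t))
}

adversary_groups <- list(
  LOWER_QUALITY_OLIVE = c("RVOO", "OPO"),
  OTHER_OILS = "OTHER",
  ADULTERATED = c("ADULT_OLIVE", "ADULT_OTHER")
)

#' Train and rank the model grid over repeated grouped splits
#'
#' For each of `n_repeats` grouped 0.8 splits of the EVOO samples, every
#' (sensor, preprocessing, algorithm) combination is tuned by grouped inner
#' cross-validation on the training EVOO measurements, fitted, and used to
#' score the held-out EVOO measurements and all non-EVOO measurements.
#' Distances are averaged per sample (and across repeats), and each model is
#' ranked by the unweighted mean of its AUROCs against the three adversary
#' groups.
#'
#' @param meas measurement set: named list per sensor with elements `X`
#'   (matrix, rows = measurements), `wavelengths`, `meta` (data frame with
#'   `sample_id`).
#' @param samples sample table with columns `sample_id`, `truth_class`
#'   (`EVOO`, `RVOO`, `OPO`, `OTHER`, `ADULT_OLIVE`, `ADULT_OTHER`).
#' @param grid model grid from [enumerate_model_grid()].
#' @param fraction,n_repeats outer split fraction and repeat count.
#' @param seed root seed.
#' @param inner_folds folds for [inner_cv_select()].
#' @return list with `performance` (data frame: `key`, `sensor`, one AUROC
#'   column per adversary group, `rank_score`), `sample_distances` (matrix
#'   samples x model keys of repeat-averaged distances), `audit` (per-repeat
#'   train/test ids for the leakage check).
#' @export
rank_model_grid <- function(meas, samples, grid, fraction = 0.8,
                            n_repeats = 5L, seed = 1L, inner_folds = 5L) {
  evoo_ids <- samples$sample_id[samples$truth_class == "EVOO"]
  keys <- as.character(t(outer(names(meas), grid$key, paste, sep = "|")))
  acc_sum <- acc_n <- matrix(0, nrow(samples), length(keys),
                             dimnames = list(samples$sample_id, keys))
  audit <- lapply(seq_len(n_repeats), function(r)
    grouped_split(evoo_ids, fraction, derive_seed(seed, "split", r)))
  for (sensor in names(meas)) {
    m <- meas[[sensor]]
    feats <- feature_cache(m, grid)
    for (r in seq_len(n_repeats)) {
      sp <- audit[[r]]
      tr_rows <- m$meta$sample_id %in% sp$train_sample_ids
      te_rows <- !tr_rows
      for (g in seq_len(nrow(grid))) {
        Fm <- feats[[preprocess_key(grid$preprocess[[g]])]]
        Xtr <- Fm[tr_rows, , drop = FALSE]
        hy <- inner_cv_select(grid$algorithm[g], Xtr,
                              m$meta$sample_id[tr_rows],
                              n_folds = inner_folds,
                              seed = derive_seed(seed, "cv", r, sensor,
                                                 grid$key[g]))
        model <- occ_fit(grid$algorithm[g], Xtr, hy)
        d <- occ_distance(model, Fm[te_rows, , drop = FALSE])
        per_sample <- aggregate_sample_distance(d,
                                                m$meta$sample_id[te_rows])
        key <- paste(sensor, grid$key[g], sep = "|")
        ids <- names(per_sample)
        acc_sum[ids, key] <- acc_sum[ids, key] + per_sample
        acc_n[ids, key] <- acc_n[ids, key] + 1
      }
    }
  }
  dist <- acc_sum / ifelse(acc_n > 0, acc_n, NA)
  truth <- stats::setNames(samples$truth_class, samples$sample_id)
  perf <- do.call(rbind, lapply(keys, function(k) {
    d <- dist[, k]
    tgt <- d[truth[names(d)] == "EVOO" & !is.na(d)]
    aur <- vapply(adversary_groups, function(cls) {
      adv <- d[truth[names(d)] %in% cls & !is.na(d)]
      auroc(tgt, adv)
    }, 0)
    data.frame(key = k, sensor = strsplit(k, "|", fixed = TRUE)[[1]][1],
               auroc_lower_quality_olive = aur[["LOWER_QUALITY_OLIVE"]],
               auroc_other_oils = aur[["OTHER_OILS"]],
               auroc_adulterated = aur[["ADULTERATED"]],
               stringsAsFactors = FALSE)
  }))
  perf$rank_score <- rowMeans(perf[, c("auroc_lower_quality_olive",
                                       "auroc_other_oils",
                                       "auroc_adulterated")])
  list(performance = perf, sample_distances = dist, audit = audit)
}

# compute (and cache) the feature matrix of every distinct preprocessing in
# the grid for one sensor's measurement matrix
feature_cache <- function(m, grid) {
  out <- list()
  for (g in seq_len(nrow(grid))) {
    k <- preprocess_key(grid$preprocess[[g]])
    if (is.null(out[[k]]))
      out[[k]] <- apply_preprocess(grid$preprocess[[g]], m$X, m$wavelengths)
  }
  out
}

#' Select the top models per sensor by quota
#'
#' Keeps, per sensor, the `quota`-many models with the highest `rank_score`
#' (mean AUROC over the three adversary groups); ties break toward the
#' lexicographically smaller model key, so selection is stable across runs.
#'
#' @param performances performance data frame from [rank_model_grid()].
#' @param quotas named integer vector, sensor -> number of models (default
#'   `c(FLUO = 6, VIS = 2, NIR = 2)`).
#' @return character vector of exactly `sum(quotas)` selected model keys.
#' @export
rank_and_select <- function(performances,
                            quotas = c(FLUO = 6L, VIS = 2L, NIR = 2L)) {
  quotas <- quotas[quotas > 0L]
  sel <- character()
  for (s in names(quotas)) {
    cand <- performances[performances$sensor == s, ]
    if (nrow(cand) < quotas[[s]])
      stop_evoofuse(sprintf("sensor %s has %d candidates for quota %d", s,
                            nrow(cand), quotas[[s]]), "selection_error")
    ord <- order(-cand$rank_score, cand$key)
    sel <- c(sel, cand$key[ord][seq_len(quotas[[s]])])
  }
  sel
}
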