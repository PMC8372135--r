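#' @title High-level decision fusion and threshold scenarios
#' @description Per-model thresholding of class distances, replicate
#'   combination, the >= 2-of-10 out-of-class voting rule, and the two
#'   decision-threshold scenarios: scenario 1 tunes each model so that no
#'   calibration EVOO is ever flagged (raw-material identification), scenario
#'   2 trades some EVOO specificity for a higher detection rate of
#'   adulterated EVOOs (fraud screening).
#' @name fusion_decision
NULL

#' Threshold a class distance into an in/out vote
#'
#' A sample votes `"out"` only when its distance strictly exceeds the
#' threshold; the boundary counts as in-class (conservative toward EVOO).
#'
#' @param distance nonnegative class distance(s).
#' @param threshold positive per-model threshold.
#' @return character vector of `"in"` / `"out"` votes.
#' @export
apply_threshold <- function(distance, threshold) {
  stopifnot(threshold > 0)
  ifelse(distance > threshold, "out", "in")
}

#' Combine replicate measurement distances into one per-sample distance
#'
#' The replicate measurements of one sample (three days x three repeats) are
#' combined before thresholding; the default policy is the arithmetic mean
#' (identical to [aggregate_sample_distance()]), `median` is available as a
#' robust alternative.
#'
#' @param per_measurement_distances numeric vector, >= 1 value.
#' @param policy `"mean"` or `"median"`.
#' @return one combined distance.
#' @export
combine_replicates <- function(per_measurement_distances,
                               policy = c("mean", "median")) {
  policy <- match.arg(policy)
  if (!length(per_measurement_distances))
    stop_evoofuse("no measurements to combine", "input_error")
  switch(policy, mean = mean(per_measurement_distances),
         median = stats::median(per_measurement_distances))
}

#' Fuse per-model votes into a final EVOO / non-EVOO flag
#'
#' @param votes character vector of `"in"`/`"out"` votes (or logicals, `TRUE`
#'   = out), one per selected model.
#' @param min_votes flag the sample as non-EVOO when at least this many
#'   models vote out (default 2, the 2-of-10 rule).
#' @return list with `votes_out` (count) and `flag` (`"EVOO"`/`"NON_EVOO"`).
#' @export
fuse_votes <- function(votes, min_votes = 2L) {
  if (!length(votes)) stop_evoofuse("empty vote list", "input_error")
  stopifnot(min_votes >= 1L)
  out <- if (is.logical(votes)) sum(votes) else sum(votes == "out")
  list(votes_out = as.integer(out),
       flag = if (out >= min_votes) "NON_EVOO" else "EVOO")
}

#' Fused decisions for a table of per-sample model distances
#'
#' @param dist matrix of combined per-sample distances, rows = samples
#'   (rownames = sample ids), columns = model keys.
#' @param thresholds named numeric vector, model key -> threshold.
#' @param min_votes fusion vote minimum.
#' @return data frame `sample_id`, `votes_out`, `flag`.
#' @export
decide_samples <- function(dist, thresholds, min_votes = 2L) {
  keys <- colnames(dist)
  stopifnot(all(keys %in% names(thresholds)))
  votes <- sweep(dist, 2L, thresholds[keys], `>`)
  votes_out <- rowSums(votes)
  data.frame(sample_id = rownames(dist), votes_out = as.integer(votes_out),
             flag = ifelse(votes_out >= min_votes, "NON_EVOO", "EVOO"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scenario configuration for threshold tuning
#'
#' @param scenario `"S1_NO_FALSE_NEGATIVE"` (all calibration EVOOs classified
#'   EVOO, by construction) or `"S2_FRAUD_SCREEN"` (maximize detection of
#'   adulterated calibration samples subject to an EVOO-rate floor).
#' @param min_votes fusion vote minimum (default 2).
#' @param evoo_rate_floor minimum fused EVOO correct rate for scenario 2.
#' @param threshold_grid quantile grid searched by scenario 2.
#' @param eps relative margin above the scenario-1 maximum.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("S1_NO_FALSE_NEGATIVE",
                                         "S2_FRAUD_SCREEN"),
                            min_votes = 2L, evoo_rate_floor = 0.75,
                            threshold_grid = seq(0.5, 1, by = 0.01),
                            eps = 1e-6) {
  scenario <- match.arg(scenario)
  stopifnot(min_votes >= 1L, evoo_rate_floor >= 0, evoo_rate_floor <= 1)
  structure(list(scenario = scenario, min_votes = as.integer(min_votes),
                 evoo_rate_floor = evoo_rate_floor,
                 threshold_grid = threshold_grid, eps = eps),
            class = "scenario_config")
}

#' Tune per-model decision thresholds for a scenario
#'
#' Scenario 1 sets each model's threshold to `(1 + eps)` times the maximum
#' calibration-EVOO per-sample distance of that model, so no calibration
#' EVOO can produce an out-vote and the fused EVOO rate is 100% by
#' construction. Scenario 2 searches a common quantile `q` of each model's
#' calibration-EVOO distances and picks the `q` maximizing the fused
#' detection rate of adulterated calibration samples subject to a fused EVOO
#' correct rate of at least `evoo_rate_floor`; ties prefer the higher EVOO
#' rate, then the lower quantile. An infeasible floor falls back to the
#' scenario-1 thresholds with a warning.
#'
#' @param calibration_distances matrix of combined per-sample distances
#'   (rows = calibration samples with rownames, columns = model keys).
#' @param labels named character vector, sample id -> truth class (`EVOO`,
#'   `ADULT_OLIVE`, `ADULT_OTHER`, ...).
#' @param config a [scenario_config()].
#' @return named numeric vector of per-model thresholds, with the chosen
#'   quantile (S2) in attribute `"quantile"`.
#' @export
tune_thresholds <- function(calibration_distances, labels, config) {
  stopifnot(inherits(config, "scenario_config"))
  ids <- rownames(calibration_distances)
  lab <- labels[ids]
  evoo <- which(lab == "EVOO")
  if (!length(evoo))
    stop_evoofuse("calibration set contains no EVOO samples",
                  "scenario_error")
  E <- calibration_distances[evoo, , drop = FALSE]
  s1 <- pmax(apply(E, 2L, max) * (1 + config$eps), config$eps)
  if (config$scenario == "S1_NO_FALSE_NEGATIVE")
    return(s1)
  adult <- which(lab %in% c("ADULT_OLIVE", "ADULT_OTHER"))
  if (!length(adult))
    stop_evoofuse("scenario 2 needs adulterated calibration samples",
                  "scenario_error")
  best <- NULL
  for (q in sort(config$threshold_grid)) {
    thr <- apply(E, 2L, stats::quantile, probs = q, names = FALSE) *
      (1 + config$eps)
    thr <- pmax(thr, config$eps)
    dec <- decide_samples(calibration_distances, thr, config$min_votes)
    flag <- stats::setNames(dec$flag, dec$sample_id)
    evoo_rate <- mean(flag[ids[evoo]] == "EVOO")
    det_rate <- mean(flag[ids[adult]] == "NON_EVOO")
    if (evoo_rate < config$evoo_rate_floor) next
    if (is.null(best) || det_rate > best$det ||
        (det_rate == best$det && evoo_rate > best$evoo)) {
      best <- list(q = q, thr = thr, det = det_rate, evoo = evoo_rate)
    }
  }
  if (is.null(best)) {
    warning("scenario-2 EVOO-rate floor infeasible on the calibration set; ",
            "falling back to scenario-1 thresholds")
    return(s1)
  }
  structure(best$thr, quantile = best$q)
}
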