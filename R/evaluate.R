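#' @title Rate tables, detection curves and reference-chemistry limits
#' @description Per-class correct-classification tables for the fused
#'   decision and each single-sensor restriction, detection rates by
#'   adulteration fraction, and the regulatory conformity checker for the
#'   wet-lab reference chemistry of EVOO.
#' @name evaluation
NULL

rate_classes <- c("EVOO", "RVOO", "OPO", "OTHER", "ADULT_OLIVE",
                  "ADULT_OTHER")

#' Per-class correct-classification rate table
#'
#' For the truth class EVOO a decision is correct when the sample is flagged
#' EVOO; for every other class (pure non-EVOO oils and admixtures at any
#' level) when it is flagged NON_EVOO. Besides the fused column, the fusion
#' is re-run restricted to each sensor's selected models with the vote
#' minimum rescaled as `max(1, round(min_votes * n_sensor / n_total))`, using
#' identical thresholds.
#'
#' @param dist per-sample distance matrix (rows = samples with rownames,
#'   columns = selected model keys, sensor encoded as the key prefix
#'   `SENSOR|...`).
#' @param thresholds named per-model thresholds from [tune_thresholds()].
#' @param truth named character vector, sample id -> truth class.
#' @param min_votes fused vote minimum (default 2).
#' @return data frame, one row per truth class present, columns `class`,
#'   `n`, `fused`, and one column per sensor (percentages in `[0, 100]`);
#'   audit numerators in attribute `"correct"`.
#' @export
rate_table <- function(dist, thresholds, truth, min_votes = 2L) {
  ids <- rownames(dist)
  if (any(!ids %in% names(truth)))
    stop_evoofuse(paste("samples without truth record:",
                        paste(setdiff(ids, names(truth)), collapse = ", ")),
                  "join_error")
  truth <- truth[ids]
  sensors <- vapply(strsplit(colnames(dist), "|", fixed = TRUE), `[`, "", 1L)
  columns <- list(fused = colnames(dist))
  for (s in unique(sensors)) columns[[s]] <- colnames(dist)[sensors == s]
  classes <- rate_classes[rate_classes %in% unique(truth)]
  res <- data.frame(class = classes,
                    n = vapply(classes, function(cl) sum(truth == cl), 0L),
                    row.names = NULL, stringsAsFactors = FALSE)
  correct <- matrix(NA_integer_, length(classes), length(columns),
                    dimnames = list(classes, names(columns)))
  for (cn in names(columns)) {
    keys <- columns[[cn]]
    mv <- if (cn == "fused") min_votes else
      max(1L, round(min_votes * length(keys) / ncol(dist)))
    dec <- decide_samples(dist[, keys, drop = FALSE], thresholds, mv)
    flag <- stats::setNames(dec$flag, dec$sample_id)
    for (cl in classes) {
      in_cl <- ids[truth == cl]
      want <- if (cl == "EVOO") "EVOO" else "NON_EVOO"
      correct[cl, cn] <- sum(flag[in_cl] == want)
    }
    res[[cn]] <- round(100 * correct[, cn] / res$n, 1)
  }
  attr(res, "correct") <- correct
  res
}

#' Detection rate by adulteration fraction
#'
#' @param decisions data frame from [decide_samples()] (needs `sample_id`,
#'   `flag`).
#' @param manifest truth manifest with columns `sample_id`,
#'   `adulterant_class`, `fraction_v` (non-adulterated rows are ignored).
#' @param fraction_bins fractions to report; defaults to those present.
#' @return data frame `adulterant_class`, `fraction`, `n`, `detected`,
#'   `rate_pct` (`NA` rate for empty bins, never zero).
#' @export
detection_by_fraction <- function(decisions, manifest, fraction_bins = NULL) {
  adm <- manifest[!is.na(manifest$fraction_v), ]
  flag <- stats::setNames(decisions$flag, decisions$sample_id)
  if (is.null(fraction_bins)) fraction_bins <- sort(unique(adm$fraction_v))
  grid <- expand.grid(adulterant_class = unique(adm$adulterant_class),
                      fraction = fraction_bins, stringsAsFactors = FALSE)
  grid$n <- grid$detected <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    ids <- adm$sample_id[adm$adulterant_class == grid$adulterant_class[i] &
                           abs(adm$fraction_v - grid$fraction[i]) < 1e-9]
    ids <- intersect(ids, names(flag))
    grid$n[i] <- length(ids)
    grid$detected[i] <- sum(flag[ids] == "NON_EVOO")
  }
  grid$rate_pct <- ifelse(grid$n > 0, 100 * grid$detected / grid$n, NA_real_)
  grid[order(grid$adulterant_class, grid$fraction), ]
}

# regulatory limits: <= for the oxidation indicators, strict < for the
# process contaminants (MCPD esters / glycidyl esters)
reference_limits <- data.frame(
  analyte = c("peroxide_index", "k232", "k268", "delta_k",
              "mcpd3", "mcpd2", "ges"),
  limit = c(20.00, 2.5, 0.22, 0.01, 0.10, 0.07, 0.07),
  strict = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

#' Check wet-lab reference chemistry against the EVOO limits
#'
#' Conformity limits for EVOO: peroxide index <= 20.00 mEq O2/kg, K232 <=
#' 2.5 AU, K268 <= 0.22 AU, Delta-K <= 0.01, and strictly < 0.10 / 0.07 /
#' 0.07 mg/kg for 3-MCPD, 2-MCPD and glycidyl esters. Values censored below
#' the detection limit (given as strings such as `"<0.10"`) pass.
#'
#' @param values named list/vector; any subset of `peroxide_index`, `k232`,
#'   `k268`, `delta_k`, `mcpd3`, `mcpd2`, `ges`. Numeric, or a `"<x"` string
#'   for censored results.
#' @return data frame `analyte`, `value`, `limit`, `pass`.
#' @export
check_reference_limits <- function(values) {
  values <- values[!vapply(values, is.null, TRUE)]
  known <- intersect(names(values), reference_limits$analyte)
  if (!length(known))
    stop_evoofuse("no known analyte present", "input_error")
  out <- reference_limits[match(known, reference_limits$analyte), ]
  out$value <- vapply(values[known], function(v)
    if (is.character(v)) NA_real_ else as.numeric(v), 0)
  censored <- vapply(values[known], function(v)
    is.character(v) && startsWith(trimws(v), "<"), TRUE)
  if (any(!censored & (is.na(out$value) | out$value < 0)))
    stop_evoofuse("analyte values must be nonnegative numbers or censored",
                  "input_error")
  out$pass <- censored |
    ifelse(out$strict, out$value < out$limit, out$value <= out$limit)
  rownames(out) <- NULL
  out[, c("analyte", "value", "limit", "pass")]
}
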