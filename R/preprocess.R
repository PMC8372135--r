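#' @title Chemometric preprocessing operators
#' @description Row-wise spectral preprocessing used to build the one-class
#'   model grid: standard normal variate (SNV), SNV + quadratic detrend,
#'   Savitzky-Golay derivatives, wavelet detail features, and splitting of the
#'   spectrum into four contiguous sections modelled separately. All operators
#'   are pure functions of the input vector.
#' @name preprocess
NULL

#' Standard normal variate
#'
#' Centers and scales one spectrum to mean 0 / sd 1 (denominator n - 1),
#' removing multiplicative scatter and additive offset effects.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return numeric vector of the same length.
#' @export
snv <- function(x) {
  stopifnot(length(x) >= 2L)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0)
    stop_evoofuse("SNV undefined for constant input", "zero_variance_error")
  (x - mean(x)) / s
}

#' SNV followed by quadratic detrending
#'
#' Applies [snv()] and then removes the least-squares quadratic baseline in
#' wavelength; the output is orthogonal to `{1, lambda, lambda^2}`.
#'
#' @param x numeric vector, length >= 4.
#' @param wavelengths numeric vector of the same length.
#' @return detrended numeric vector.
#' @export
snv_detrend <- function(x, wavelengths) {
  if (length(x) < 4L)
    stop_evoofuse("quadratic detrend needs >= 4 points",
                  "underdetermined_fit_error")
  stopifnot(length(wavelengths) == length(x))
  z <- snv(x)
  # orthogonal polynomial basis keeps the normal equations well conditioned
  fit <- stats::lm.fit(cbind(1, stats::poly(wavelengths, 2)), z)
  fit$residuals
}

#' Savitzky-Golay derivative
#'
#' First or second derivative with an 11-point window and quadratic fitting
#' polynomial (the minimal degree exact for both requested orders). Edge
#' points where the window does not fit are dropped, so the output is 10
#' points shorter than the input. A uniform wavelength spacing is assumed.
#'
#' @param x numeric vector, length >= 11.
#' @param deriv_order 1 or 2.
#' @param spacing grid spacing in nm (derivatives are per nm).
#' @param window odd window length (default 11).
#' @return numeric vector of length `length(x) - window + 1`.
#' @export
sg_derivative <- function(x, deriv_order, spacing = 1, window = 11L) {
  deriv_order <- as.integer(deriv_order)
  stopifnot(deriv_order %in% 1:2, window %% 2L == 1L, spacing > 0)
  n <- length(x)
  if (n < window)
    stop_evoofuse(sprintf("need >= %d points for the SG window", window),
                  "window_error")
  fm <- signal::sgolay(p = 2, n = window, m = deriv_order, ts = spacing)
  w <- fm[(window + 1L) %/% 2L, ]          # central (interior) filter row
  half <- (window - 1L) %/% 2L
  idx <- (half + 1L):(n - half)
  vapply(idx, function(i) sum(w * x[(i - half):(i + half)]), 0)
}

# -- periodized orthonormal DWT ----------------------------------------------

# decomposition low-pass filters; the least-asymmetric length-8 filter
# (symlet-4) uses the standard published coefficients
dwt_filters <- list(
  daubechies_len2 = c(0.7071067811865476, 0.7071067811865476),
  least_asymmetric_len8 = c(-0.07576571478927333, -0.02963552764599851,
                            0.49761866763201545, 0.8037387518059161,
                            0.29785779560527736, -0.09921954357684722,
                            -0.012603967262037833, 0.0322231006040427)
)

# one periodized analysis step: x (even length) -> list(approx, detail)
dwt_step <- function(x, h) {
  n <- length(x)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)     # quadrature mirror filter
  k <- seq.int(0L, n - 2L, by = 2L)
  idx <- outer(k, 0L:(L - 1L), `+`) %% n + 1L
  xm <- matrix(x[idx], nrow = length(k))
  list(approx = as.numeric(xm %*% h), detail = as.numeric(xm %*% g))
}

# full decomposition to `nlevels`; returns details[[j]] for j = 1..nlevels
# plus the final approximation (orthonormal, so energy is conserved)
dwt_periodic <- function(x, family, nlevels) {
  h <- dwt_filters[[family]]
  if (is.null(h)) stop_evoofuse("unknown wavelet family", "config_error")
  details <- vector("list", nlevels)
  a <- x
  for (j in seq_len(nlevels)) {
    if (length(a) %% 2L != 0L)
      stop_evoofuse("dyadic length required for periodized DWT",
                    "config_error")
    st <- dwt_step(a, h)
    details[[j]] <- st$detail
    a <- st$approx
  }
  list(details = details, approx = a)
}

#' Wavelet detail features of a spectrum
#'
#' Interpolates the spectrum linearly onto 128 equally spaced points over its
#' wavelength range, applies a periodized orthonormal discrete wavelet
#' transform, and concatenates the detail coefficients of the requested
#' levels (coarser levels last). Defaults follow the two configurations of
#' the model grid: Daubechies length-2 (Haar) levels 5-7 (4 + 2 + 1 = 7
#' coefficients) and least-asymmetric length-8 (symlet-4) levels 3-5
#' (16 + 8 + 4 = 28 coefficients).
#'
#' @param x numeric vector, length >= 2.
#' @param family `"daubechies_len2"` or `"least_asymmetric_len8"`.
#' @param levels integer vector of detail levels; defaults per family.
#' @param n_interp number of interpolation points (power of two).
#' @return numeric feature vector.
#' @export
dwt_features <- function(x, family = c("daubechies_len2",
                                       "least_asymmetric_len8"),
                         levels = NULL, n_interp = 128L) {
  family <- match.arg(family)
  stopifnot(length(x) >= 2L)
  if (is.null(levels))
    levels <- if (family == "daubechies_len2") 5:7 else 3:5
  if (log2(n_interp) %% 1 != 0)
    stop_evoofuse("n_interp must be a power of two", "config_error")
  if (max(levels) > log2(n_interp))
    stop_evoofuse("requested level exceeds log2(n_interp)", "config_error")
  xi <- stats::approx(seq_along(x), x, n = n_interp)$y
  dec <- dwt_periodic(xi, family, max(levels))
  unlist(dec$details[levels], use.names = FALSE)
}

#' Split a spectrum into one of four equal-length sections
#'
#' Returns the `section`-th of four contiguous sections; when the length is
#' not divisible by 4 the first `length %% 4` sections get one extra point,
#' so the four sections always concatenate back to the input exactly.
#'
#' @param x numeric vector, length >= 4.
#' @param section integer in 1..4.
#' @return the contiguous subvector.
#' @export
split_spectrum <- function(x, section) {
  idx <- split_indices(length(x), section)
  x[idx]
}

#' @rdname split_spectrum
#' @param n input length.
#' @return `split_indices` returns the integer index range of the section.
#' @export
split_indices <- function(n, section) {
  if (!(section %in% 1:4))
    stop_evoofuse("section must be in 1..4", "config_error")
  stopifnot(n >= 4L)
  base <- n %/% 4L
  extra <- n %% 4L
  sizes <- rep(base, 4L) + c(rep(1L, extra), rep(0L, 4L - extra))
  to <- cumsum(sizes)
  from <- to - sizes + 1L
  seq.int(from[section], to[section])
}

# -- preprocessing specifications and the model grid -------------------------

pp_step_names <- c("none", "snv", "snv_detrend", "sg1", "sg2",
                   "dwt_haar", "dwt_la8")

#' Preprocessing specification
#'
#' An ordered list of preprocessing steps plus an optional spectral-split
#' section. Splitting, when present, is applied first (each section is
#' preprocessed and modelled separately).
#'
#' @param steps character vector from `none`, `snv`, `snv_detrend`, `sg1`,
#'   `sg2` (Savitzky-Golay 1st/2nd derivative, 11-point window),
#'   `dwt_haar` (Haar details, levels 5-7), `dwt_la8` (least-asymmetric
#'   length-8 details, levels 3-5).
#' @param split `NULL` for the full spectrum or a section index 1..4.
#' @return object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(steps = "none", split = NULL) {
  steps <- as.character(steps)
  bad <- setdiff(steps, pp_step_names)
  if (length(bad))
    stop_evoofuse(paste("unknown preprocessing step:",
                        paste(bad, collapse = ", ")), "config_error")
  if (!is.null(split) && !(split %in% 1:4))
    stop_evoofuse("split must be NULL or 1..4", "config_error")
  structure(list(steps = steps,
                 split = if (is.null(split)) NULL else as.integer(split)),
            class = "preprocess_spec")
}

#' Canonical string key of a preprocessing spec
#' @param spec a [preprocess_spec()].
#' @return character scalar, stable across runs (used in model registries).
#' @export
preprocess_key <- function(spec) {
  paste0(if (is.null(spec$split)) "full" else paste0("split", spec$split),
         "+", paste(spec$steps, collapse = "+"))
}

apply_step <- function(step, x, wavelengths) {
  switch(step,
    none = x,
    snv = snv(x),
    snv_detrend = snv_detrend(x, wavelengths),
    sg1 = sg_derivative(x, 1L, spacing = mean(diff(wavelengths))),
    sg2 = sg_derivative(x, 2L, spacing = mean(diff(wavelengths))),
    dwt_haar = dwt_features(x, "daubechies_len2"),
    dwt_la8 = dwt_features(x, "least_asymmetric_len8"),
    stop_evoofuse(paste("unknown step", step), "config_error"))
}

#' Apply a preprocessing spec to one spectrum or a spectra matrix
#'
#' @param spec a [preprocess_spec()].
#' @param x numeric vector (one spectrum) or matrix (rows = spectra).
#' @param wavelengths wavelength grid matching `ncol(x)`/`length(x)`.
#' @return feature vector, or feature matrix with one row per input row.
#' @export
apply_preprocess <- function(spec, x, wavelengths) {
  one <- function(v) {
    w <- wavelengths
    if (!is.null(spec$split)) {
      idx <- split_indices(length(v), spec$split)
      v <- v[idx]; w <- w[idx]
    }
    for (st in spec$steps) {
      v <- apply_step(st, v, w)
      w <- switch(st,
                  sg1 = , sg2 = w[6:(length(w) - 5)],
                  dwt_haar = , dwt_la8 = seq_along(v),
                  w)
    }
    v
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, one))
    if (nrow(x) == 1L) out <- matrix(out, nrow = 1L)
    rownames(out) <- rownames(x)
    out
  } else one(x)
}

#' Enumerate the one-class model grid
#'
#' Cartesian enumeration of the enabled (preprocessing, split-or-full,
#' algorithm) combinations, deduplicated by canonical key, in a deterministic
#' order. The default configuration (6 preprocessings x full-spectrum + 4
#' splits x 5 algorithms) yields 150 combinations per sensor.
#'
#' @param preprocess list of step vectors (each one entry of the grid).
#' @param splits vector of split options; `NA` means full spectrum.
#' @param algorithms character vector of one-class algorithms.
#' @return data frame with columns `key`, `preprocess` (list column of
#'   [preprocess_spec()]), `algorithm`.
#' @export
enumerate_model_grid <- function(preprocess = list("snv", "snv_detrend",
                                                   "sg1", "sg2", "dwt_haar",
                                                   "dwt_la8"),
                                 splits = c(NA, 1, 2, 3, 4),
                                 algorithms = c("SIMCA", "KNN", "PCA_RESIDUAL",
                                                "MAHALANOBIS", "OCSVM_RBF")) {
  if (!length(preprocess) || !length(splits) || !length(algorithms))
    stop_evoofuse("empty model grid configuration", "config_error")
  specs <- list(); keys <- character(); algs <- character()
  for (alg in algorithms) for (sp in splits) for (pp in preprocess) {
    spec <- preprocess_spec(pp, split = if (is.na(sp)) NULL else sp)
    key <- paste0(alg, "|", preprocess_key(spec))
    if (key %in% keys) next
    keys <- c(keys, key); specs <- c(specs, list(spec)); algs <- c(algs, alg)
  }
  ord <- order(keys)
  out <- data.frame(key = keys[ord], algorithm = algs[ord],
                    stringsAsFactors = FALSE)
  out$preprocess <- specs[ord]
  out
}
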