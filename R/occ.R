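#' @title One-class classifiers with a common fit/score contract
#' @description Five one-class algorithms, each trained on EVOO feature rows
#'   only and emitting a nonnegative class distance (larger = less
#'   EVOO-like): SIMCA (combined normalized orthogonal/score distance), kNN
#'   mean neighbour distance, PCA orthogonal residual (Q), regularized
#'   Mahalanobis distance, and a one-class SVM with RBF kernel. Fitting goes
#'   through [occ_fit()] and scoring through [occ_distance()].
#' @name occ_models
NULL

occ_algorithms <- c("SIMCA", "KNN", "PCA_RESIDUAL", "MAHALANOBIS",
                    "OCSVM_RBF")

# thin PCA of the mean-centered training matrix via SVD
pca_basis <- function(X, n_components) {
  n <- nrow(X)
  if (n_components < 1L || n_components > min(n - 1L, ncol(X)))
    stop_evoofuse("n_components out of range", "hyperparameter_error")
  mu <- colMeans(X)
  sv <- svd(sweep(X, 2L, mu), nu = 0, nv = n_components)
  scores <- sweep(X, 2L, mu) %*% sv$v
  list(mean = mu, loadings = sv$v,
       score_var = apply(scores, 2L, stats::var),
       n_components = n_components)
}

pca_qh <- function(basis, X) {
  Xc <- sweep(X, 2L, basis$mean)
  t_scores <- Xc %*% basis$loadings
  resid <- Xc - t_scores %*% t(basis$loadings)
  q <- rowSums(resid^2)
  h <- rowSums(sweep(t_scores^2, 2L, pmax(basis$score_var, 1e-300), `/`))
  list(q = q, h = h)
}

#' Fit a SIMCA one-class model
#'
#' Mean-centered PCA of the EVOO training features; each sample gets an
#' orthogonal distance `q` (squared residual norm off the PCA subspace) and a
#' score distance `h` (Hotelling leverage, squared scores over the score
#' variances). Both are normalized by their training means `q0`, `h0` and
#' combined into `d = sqrt((q/q0)^2 + (h/h0)^2)`. If the training residuals
#' vanish (components = rank), the q-term is dropped.
#'
#' @param train numeric matrix, training feature rows (EVOO only), >= 5 rows.
#' @param n_components number of principal components.
#' @return a trained model usable with [occ_distance()].
#' @export
fit_simca <- function(train, n_components) {
  stopifnot(nrow(train) >= 5L)
  basis <- pca_basis(train, n_components)
  qh <- pca_qh(basis, train)
  structure(list(basis = basis, q0 = mean(qh$q), h0 = mean(qh$h)),
            class = c("occ_simca", "occ_model"))
}

#' @export
occ_distance.occ_simca <- function(model, x, ...) {
  qh <- pca_qh(model$basis, as_feature_matrix(x))
  qn <- if (model$q0 > 1e-12) (qh$q / model$q0)^2 else 0
  hn <- if (model$h0 > 1e-12) (qh$h / model$h0)^2 else 0
  sqrt(qn + hn)
}

#' Fit a kNN one-class model
#'
#' The class distance of a query is the mean Euclidean distance to its `k`
#' nearest EVOO training rows.
#'
#' @param train training feature matrix.
#' @param k_neighbors neighbourhood size, `1 <= k <= nrow(train)`.
#' @return a trained model usable with [occ_distance()].
#' @export
fit_knn_occ <- function(train, k_neighbors) {
  k <- as.integer(k_neighbors)
  if (k < 1L || k > nrow(train))
    stop_evoofuse("k out of range", "hyperparameter_error")
  structure(list(train = train, k = k),
            class = c("occ_knn", "occ_model"))
}

cross_dist <- function(A, B) {
  # pairwise Euclidean distances, rows of A vs rows of B
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' @export
occ_distance.occ_knn <- function(model, x, ...) {
  D <- cross_dist(as_feature_matrix(x), model$train)
  apply(D, 1L, function(r) mean(sort(r)[seq_len(model$k)]))
}

#' Fit a PCA-residual (Q residual) one-class model
#'
#' Distance is the squared norm of the query's residual after projection
#' onto the mean-centered training PCA subspace.
#'
#' @inheritParams fit_simca
#' @return a trained model usable with [occ_distance()].
#' @export
fit_pca_residual <- function(train, n_components) {
  stopifnot(nrow(train) >= 5L)
  structure(list(basis = pca_basis(train, n_components)),
            class = c("occ_pca_residual", "occ_model"))
}

#' @export
occ_distance.occ_pca_residual <- function(model, x, ...) {
  pca_qh(model$basis, as_feature_matrix(x))$q
}

#' Fit a regularized Mahalanobis one-class model
#'
#' Distance `sqrt((x - mu)' S^-1 (x - mu))` with the shrunk covariance
#' `S = Sigma + lambda * tr(Sigma)/p * I`. Shrinkage is required because the
#' spectra have far more wavelengths than EVOO training samples, making the
#' sample covariance singular. Features are column-standardized by default
#' for conditioning.
#'
#' @param train training feature matrix, >= 2 rows.
#' @param regularization shrinkage weight `lambda` (default 1e-3).
#' @param standardize column-standardize features before fitting.
#' @return a trained model usable with [occ_distance()].
#' @export
fit_mahalanobis <- function(train, regularization = 1e-3,
                            standardize = TRUE) {
  stopifnot(nrow(train) >= 2L)
  std <- make_standardizer(train, standardize)
  Z <- std$apply(train)
  p <- ncol(Z)
  S <- stats::cov(Z)
  S <- S + regularization * sum(diag(S)) / p * diag(p)
  ch <- tryCatch(chol(S), error = function(e)
    stop_evoofuse("covariance singular after shrinkage",
                  "conditioning_error"))
  structure(list(mean = colMeans(Z), chol = ch, std = std),
            class = c("occ_mahalanobis", "occ_model"))
}

#' @export
occ_distance.occ_mahalanobis <- function(model, x, ...) {
  Z <- sweep(model$std$apply(as_feature_matrix(x)), 2L, model$mean)
  w <- backsolve(model$chol, t(Z), transpose = TRUE)
  sqrt(colSums(w^2))
}

#' Fit a one-class SVM with RBF kernel
#'
#' `nu`-one-class SVM; `gamma = "auto"` uses the median heuristic
#' `1 / (2 * median squared pairwise training distance)`. The class distance
#' is the decision-function deficit `max(0, rho - f(x))`, so points on the
#' in-class side score exactly 0.
#'
#' @param train training feature matrix.
#' @param nu upper bound on the training outlier fraction, in (0, 1).
#' @param gamma RBF width or `"auto"` (median heuristic).
#' @param standardize column-standardize features before fitting.
#' @return a trained model usable with [occ_distance()].
#' @export
fit_ocsvm <- function(train, nu = 0.1, gamma = "auto", standardize = TRUE) {
  stopifnot(nu > 0, nu < 1)
  std <- make_standardizer(train, standardize)
  Z <- std$apply(train)
  if (identical(gamma, "auto")) {
    d2 <- cross_dist(Z, Z)^2
    med <- stats::median(d2[upper.tri(d2)])
    if (!is.finite(med) || med <= 0)
      stop_evoofuse("degenerate kernel: all training points identical",
                    "conditioning_error")
    gamma <- 1 / (2 * med)
  }
  stopifnot(gamma > 0)
  fit <- e1071::svm(Z, y = NULL, type = "one-classification",
                    kernel = "radial", nu = nu, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, std = std, gamma = gamma, nu = nu),
            class = c("occ_ocsvm", "occ_model"))
}

#' @export
occ_distance.occ_ocsvm <- function(model, x, ...) {
  Z <- model$std$apply(as_feature_matrix(x))
  dv <- attr(stats::predict(model$fit, Z, decision.values = TRUE),
             "decision.values")
  pmax(0, -as.numeric(dv))   # decision value = f(x) - rho; deficit below rho
}

make_standardizer <- function(train, standardize) {
  if (standardize) {
    ctr <- colMeans(train)
    scl <- pmax(apply(train, 2L, stats::sd), 1e-12)
    list(apply = function(X) sweep(sweep(X, 2L, ctr), 2L, scl, `/`))
  } else list(apply = function(X) X)
}

as_feature_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Class distance of query features under a trained one-class model
#' @param model a trained model from one of the `fit_*` functions or
#'   [occ_fit()].
#' @param x numeric vector (one query) or matrix (rows = queries).
#' @param ... unused.
#' @return numeric vector of nonnegative class distances.
#' @export
occ_distance <- function(model, x, ...) UseMethod("occ_distance")

#' Fit any of the five one-class algorithms by name
#'
#' @param algorithm one of `SIMCA`, `KNN`, `PCA_RESIDUAL`, `MAHALANOBIS`,
#'   `OCSVM_RBF`.
#' @param train training feature matrix (EVOO rows only).
#' @param hyper named list of algorithm hyperparameters (`n_components`,
#'   `k_neighbors`, `regularization`, `nu`, `gamma`).
#' @return a trained model usable with [occ_distance()].
#' @export
occ_fit <- function(algorithm, train, hyper = list()) {
  algorithm <- match.arg(algorithm, occ_algorithms)
  switch(algorithm,
    SIMCA = fit_simca(train, hyper$n_components %||% 2L),
    KNN = fit_knn_occ(train, hyper$k_neighbors %||% 3L),
    PCA_RESIDUAL = fit_pca_residual(train, hyper$n_components %||% 2L),
    MAHALANOBIS = fit_mahalanobis(train,
                                  hyper$regularization %||% 1e-3),
    OCSVM_RBF = fit_ocsvm(train, hyper$nu %||% 0.1,
                          hyper$gamma %||% "auto"))
}

#' Default hyperparameter candidate grids
#'
#' SIMCA and PCA-residual search the number of components, kNN the
#' neighbourhood size; Mahalanobis and the one-class SVM have fixed defaults
#' (shrinkage 1e-3; nu = 0.1 with median-heuristic gamma).
#'
#' @param algorithm algorithm name.
#' @param n_train,n_features training dimensions, used to cap candidates.
#' @return list of hyperparameter lists, ordered by increasing complexity.
#' @export
occ_candidates <- function(algorithm, n_train, n_features) {
  algorithm <- match.arg(algorithm, occ_algorithms)
  switch(algorithm,
    SIMCA = ,
    PCA_RESIDUAL = {
      kmax <- min(5L, n_train - 2L, n_features)
      lapply(seq_len(max(kmax, 1L)), function(k) list(n_components = k))
    },
    KNN = lapply(c(1L, 3L, 5L)[c(1L, 3L, 5L) <= n_train],
                 function(k) list(k_neighbors = k)),
    MAHALANOBIS = list(list(regularization = 1e-3)),
    OCSVM_RBF = list(list(nu = 0.1, gamma = "auto")))
}

#' Grouped five-fold hyperparameter selection
#'
#' Splits the distinct training samples into five folds (all measurement
#' rows of one sample stay in one fold), fits each candidate on four folds
#' and scores the held-out EVOO rows, and returns the candidate with the
#' smallest mean held-out class distance. Ties break toward the earlier
#' (lower-complexity) candidate.
#'
#' @param algorithm algorithm name.
#' @param train training feature matrix (EVOO rows).
#' @param grouped_sample_ids sample id of each training row.
#' @param candidate_grid list of hyperparameter lists, ordered by increasing
#'   complexity; defaults to [occ_candidates()].
#' @param n_folds number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return the selected hyperparameter list, with the per-candidate CV means
#'   in attribute `"cv_means"`.
#' @export
inner_cv_select <- function(algorithm, train, grouped_sample_ids,
                            candidate_grid = NULL, n_folds = 5L, seed = 1L) {
  ids <- unique(grouped_sample_ids)
  if (is.null(candidate_grid))
    candidate_grid <- occ_candidates(algorithm, nrow(train), ncol(train))
  if (length(candidate_grid) == 1L)
    return(structure(candidate_grid[[1L]], cv_means = NA_real_))
  if (length(ids) < n_folds)
    stop_evoofuse("need at least as many distinct samples as folds",
                  "fold_error")
  fold_of <- withr::with_seed(seed,
    stats::setNames(sample(rep_len(seq_len(n_folds), length(ids))), ids))
  row_fold <- fold_of[grouped_sample_ids]
  cv_mean <- vapply(candidate_grid, function(hy) {
    held <- vapply(seq_len(n_folds), function(f) {
      tr <- train[row_fold != f, , drop = FALSE]
      te <- train[row_fold == f, , drop = FALSE]
      ok <- tryCatch({
        m <- occ_fit(algorithm, tr, hy)
        mean(occ_distance(m, te))
      }, error = function(e) NA_real_)
      ok
    }, 0)
    mean(held)
  }, 0)
  cv_mean[is.na(cv_mean)] <- Inf
  best <- which.min(cv_mean)   # which.min takes the first minimum: ties
  structure(candidate_grid[[best]], cv_means = cv_mean)
}
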