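#' PCA reduction of ROI-pair connectivity features
#'
#' Columns are mean-centered across subjects (no feature scaling); scores are
#' the projections onto the top eigenvectors of the subject-space covariance.
#' The default component count is the number of eigenvalues exceeding
#' `1e-10` times the largest — for n subjects in general position that is
#' `n - 1` (e.g. 19 subjects with 153 features give 18 components).
#'
#' @param features subjects x features numeric matrix (no missing values).
#' @param n_components requested components; `NULL` (default) keeps every
#'   non-zero eigenvalue; requests beyond the rank are truncated with a
#'   warning.
#' @return subjects x k score matrix with attributes `"eigenvalues"` (all
#'   non-zero, descending) and `"rotation"` (features x k loadings).
#' @export
pca_reduce <- function(features, n_components = NULL) {
  X <- as.matrix(features)
  if (nrow(X) < 2L) stop("PCA needs >= 2 subjects")
  if (anyNA(X)) stop("feature table contains missing values")
  Xc <- sweep(X, 2L, colMeans(X), "-")
  sv <- svd(Xc)
  ev <- sv$d^2
  rank <- sum(ev > 1e-10 * max(ev, 0))
  k <- if (is.null(n_components)) rank else as.integer(n_components)
  if (k > rank) {
    warning(sprintf("requested %d components but rank is %d; truncating",
                    k, rank))
    k <- rank
  }
  if (k == 0L)
    return(structure(matrix(numeric(0), nrow(X), 0),
                     eigenvalues = numeric(0)))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(scores, eigenvalues = ev[seq_len(rank)],
            rotation = sv$v[, seq_len(k), drop = FALSE])
}

#' Ridge regression fit on standardized predictors
#'
#' Predictors are standardized by the training means and standard deviations;
#' the coefficients solve `(Z'Z + K I) b = Z'(y - ybar)` on the standardized
#' design `Z`. The returned parameters exclude the intercept: predictions for
#' new data are `z_new . b` with `z_new` standardized by the training
#' parameters.
#'
#' @param X training score matrix (subjects x predictors).
#' @param y training outcomes.
#' @param K ridge penalty (default 5); `K = 0` is OLS on the standardized
#'   design.
#' @return list with `coef`, `center`, `scale`, `K` (class `ridge_fit`).
#' @export
ridge_fit <- function(X, y, K = 5) {
  X <- as.matrix(X)
  if (K < 0) stop("ridge penalty K must be >= 0")
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  bad <- sdv <= 0 | !is.finite(sdv)
  if (any(bad))
    stop(sprintf("zero-variance training predictor(s): %s",
                 paste(colnames(X)[bad] %||% which(bad), collapse = ", ")))
  Z <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
  A <- crossprod(Z)
  diag(A) <- diag(A) + K
  b <- solve(A, crossprod(Z, y - mean(y)))
  structure(list(coef = as.vector(b), center = mu, scale = sdv, K = K),
            class = "ridge_fit")
}

#' @export
predict.ridge_fit <- function(object, newdata, ...) {
  Z <- sweep(sweep(as.matrix(newdata), 2L, object$center, "-"),
             2L, object$scale, "/")
  as.vector(Z %*% object$coef)
}

#' Leave-one-out cross-validated ridge prediction
#'
#' Each subject is held out once; a [ridge_fit()] on the remaining subjects
#' predicts the held-out outcome (standardization by training parameters, no
#' intercept applied). `r_obs` is the Pearson correlation between the
#' predicted and observed outcomes. A zero-variance prediction vector yields
#' `r_obs = 0` with attribute `"degenerate" = TRUE`. Deterministic.
#'
#' @param scores subjects x predictors matrix (e.g. PCA scores).
#' @param behavior per-subject outcome.
#' @param K ridge penalty (default 5).
#' @return list with `predicted`, `observed`, `r_obs`, `K`.
#' @export
loocv_predict <- function(scores, behavior, K = 5) {
  X <- as.matrix(scores)
  n <- nrow(X)
  if (n < 4) stop("LOOCV needs >= 4 subjects")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- ridge_fit(X[-i, , drop = FALSE], behavior[-i], K = K)
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  r <- if (stats::sd(pred) == 0) {
    warning("zero-variance LOOCV predictions; r_obs set to 0")
    structure(0, degenerate = TRUE)
  } else stats::cor(pred, behavior)
  list(predicted = pred, observed = behavior, r_obs = as.numeric(r), K = K,
       degenerate = isTRUE(attr(r, "degenerate")))
}

# Precompute the linear maps m_i with LOOCV prediction pred_i = m_i . y:
# the ridge prediction for held-out subject i is linear in the training
# outcomes (standardization and the penalized solve depend on X only), so
# permutations can reuse one n x n matrix M (zero diagonal; training-mean
# centering folded in). Exact algebra, identical to loocv_predict.
loocv_linear_map <- function(X, K = 5) {
  X <- as.matrix(X)
  n <- nrow(X)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    mu <- colMeans(Xi)
    sdv <- apply(Xi, 2L, stats::sd)
    if (any(sdv <= 0))
      stop("zero-variance training predictor in a LOOCV fold")
    Z <- sweep(sweep(Xi, 2L, mu, "-"), 2L, sdv, "/")
    A <- crossprod(Z)
    diag(A) <- diag(A) + K
    z0 <- (X[i, ] - mu) / sdv
    wrow <- as.vector(crossprod(z0, solve(A, t(Z))))  # length n-1
    M[i, -i] <- wrow - sum(wrow) / (n - 1)            # subtracts ybar_train
  }
  M
}

#' Permutation test for the LOOCV prediction correlation
#'
#' `r_obs` is computed on the unshuffled data; for each of `B` permutations
#' the behavior labels are shuffled uniformly at random (with replacement
#' from the permutation group) and the full LOOCV ridge procedure is rerun on
#' the fixed score matrix (the label-free PCA is not recomputed). The
#' one-sided p value is `(1 + #{r_b >= r_obs}) / (B + 1)`. Degenerate
#' permuted fits (zero-variance predictions) contribute `r = 0`, keeping `B`
#' fixed.
#'
#' @param scores subjects x predictors matrix.
#' @param behavior per-subject outcome.
#' @param K ridge penalty (default 5).
#' @param B number of permutations (default 10000).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A `prediction_outcome`: list with `predicted`, `observed`,
#'   `r_obs`, `p_perm`, `perm_summary` (count, mean, quantiles), `K`, `B`,
#'   `n_components`, `seed`, and `perm_r` (the full null sample).
#' @export
permutation_test <- function(scores, behavior, K = 5, B = 10000,
                             seed = NULL) {
  if (B < 1) stop("B must be >= 1")
  obs <- loocv_predict(scores, behavior, K = K)
  M <- loocv_linear_map(scores, K = K)
  if (!is.null(seed)) {
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
  }
  n <- length(behavior)
  perm_r <- numeric(B)
  for (b in seq_len(B)) {
    yp <- behavior[sample.int(n)]
    pr <- as.vector(M %*% yp)
    perm_r[b] <- if (stats::sd(pr) == 0) 0 else stats::cor(pr, yp)
  }
  p_perm <- (1 + sum(perm_r >= obs$r_obs)) / (B + 1)
  structure(list(predicted = obs$predicted, observed = obs$observed,
                 r_obs = obs$r_obs, p_perm = p_perm,
                 perm_summary = c(count = B, mean = mean(perm_r),
                                  stats::quantile(perm_r,
                                                  c(0.05, 0.5, 0.95))),
                 K = K, B = B, n_components = ncol(as.matrix(scores)),
                 seed = seed, perm_r = perm_r),
            class = "prediction_outcome")
}

#' @export
print.prediction_outcome <- function(x, ...) {
  cat(sprintf("<prediction_outcome> r_obs = %.4f, p_perm = %.4g (B = %d, K = %g, %d components)\n",
              x$r_obs, x$p_perm, x$B, x$K, x$n_components))
  invisible(x)
}
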