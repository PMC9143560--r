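#' Weighted ridge regression via singular value decomposition
#'
#' Minimizes `(1/(2n)) * sum_i w_i (y_i - b0 - x_i'b)^2 + (lambda/2) * sum_j b_j^2`
#' with an unpenalized intercept. Columns are standardized internally
#' (weighted mean 0, weighted SD 1) by default and coefficients returned on
#' the input scale; the solution is computed from one economy SVD of the
#' square-root-weighted design, which is stable for `p > n` whenever
#' `lambda_ridge > 0`.
#'
#' @param X numeric design matrix (n x p) with column names.
#' @param y numeric outcome.
#' @param lambda_ridge ridge penalty on the `1/n` loss scale (>= 0).
#' @param obs_weights positive per-observation weights (default 1); only
#'   relative magnitudes matter.
#' @param standardize scale columns to weighted unit SD (default `TRUE`);
#'   weighted centering always happens.
#' @return A list with `beta` (input scale), `intercept`, `beta_std`
#'   (standardized scale, used for adaptive penalty weights), and
#'   `lambda_ridge`.
#' @export
ridge_fit <- function(X, y, lambda_ridge, obs_weights = NULL, standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 observations")
  if (lambda_ridge < 0) stop("lambda_ridge must be >= 0")
  w <- normalize_weights(obs_weights, n)
  std <- prep_design(X, y, w, standardize)

  sv <- svd(sqrt(w) * std$X)
  if (lambda_ridge == 0 && min(sv$d) < max(sv$d) * 1e-10)
    stop("lambda_ridge = 0 with a rank-deficient design")
  shrink <- sv$d / (sv$d^2 + n * lambda_ridge)
  beta_std <- as.numeric(sv$v %*% (shrink * crossprod(sv$u, sqrt(w) * std$yc)))
  beta <- beta_std / std$scale
  names(beta) <- names(beta_std) <- colnames(X)
  list(beta = beta,
       intercept = std$ybar - sum(beta * std$center),
       beta_std = beta_std, lambda_ridge = lambda_ridge)
}

#' Cross-validated choice of the ridge penalty
#'
#' Selects the ridge penalty minimizing mean out-of-fold weighted MSE over a
#' log-spaced grid. One SVD per fold evaluates the entire grid exactly. Ties
#' resolve to the largest penalty.
#'
#' @inheritParams ridge_fit
#' @param folds number of CV folds (default 10).
#' @param grid penalty grid (default `10^seq(-4, 3, length.out = 15)`).
#' @param seed integer seed for the fold partition.
#' @param fold_id optional explicit fold assignment (overrides `seed`).
#' @return A list with `lambda_ridge` (the chosen value), `grid`, `cv_mean`,
#'   `cv_se`, and `fold_id`.
#' @export
ridge_cv <- function(X, y, folds = 10, grid = 10^seq(-4, 3, length.out = 15),
                     seed = 1, obs_weights = NULL, standardize = TRUE,
                     fold_id = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(grid) == 0) stop("empty ridge grid")
  if (is.null(fold_id)) fold_id <- make_folds(n, folds, seed)
  k <- max(fold_id)
  w <- normalize_weights(obs_weights, n)
  grid <- sort(grid, decreasing = TRUE)

  mse <- matrix(NA_real_, length(grid), k)
  for (f in seq_len(k)) {
    tr <- fold_id != f
    nt <- sum(tr)
    wt <- normalize_weights(w[tr], nt)
    std <- prep_design(X[tr, , drop = FALSE], y[tr], wt, standardize)
    sv <- svd(sqrt(wt) * std$X)
    uty <- crossprod(sv$u, sqrt(wt) * std$yc)
    Xte <- X[!tr, , drop = FALSE]
    for (g in seq_along(grid)) {
      beta_std <- as.numeric(sv$v %*% ((sv$d / (sv$d^2 + nt * grid[g])) * uty))
      beta <- beta_std / std$scale
      pred <- std$ybar - sum(beta * std$center) + as.numeric(Xte %*% beta)
      wo <- w[!tr]
      mse[g, f] <- sum(wo * (y[!tr] - pred)^2) / sum(wo)
    }
  }
  cv_mean <- rowMeans(mse)
  cv_se <- apply(mse, 1L, sd) / sqrt(k)
  best <- which(cv_mean == min(cv_mean))[1L]  # grid descending: ties -> largest
  list(lambda_ridge = grid[best], grid = grid, cv_mean = cv_mean,
       cv_se = cv_se, fold_id = fold_id)
}

#' Adaptive penalty factors from ridge coefficients
#'
#' The adaptive LASSO penalizes feature `j` proportionally to
#' `1 / |beta_ridge_j|`, so features with strong initial signal are shrunk
#' less. Near-zero ridge coefficients are capped to keep the factors finite.
#'
#' @param ridge_beta initial (ridge) coefficients; standardized-scale
#'   coefficients should be used when the LASSO standardizes internally.
#' @param cap maximum penalty factor (default 1e6).
#' @return Positive finite penalty factors, named like `ridge_beta`.
#' @export
penalty_weights <- function(ridge_beta, cap = 1e6) {
  if (any(!is.finite(ridge_beta))) stop("ridge coefficients must be finite")
  pmin(1 / abs(ridge_beta), cap)
}

#' Regularization path grid
#'
#' Computes `lambda_max`, the smallest penalty at which every penalized
#' coefficient is zero: `max_j |<x_j, y - ybar>_w| / (n * v_j)` over features
#' with positive finite penalty factor `v_j`, on the internally standardized
#' scale. Returns a log-spaced descending grid from `lambda_max` down to
#' `lambda_max * lambda_min_ratio`.
#'
#' @inheritParams ridge_fit
#' @param penalty_factors per-feature penalty factors (`Inf` excludes a
#'   feature; 0 leaves it unpenalized and outside the `lambda_max`
#'   computation).
#' @param n_lambda grid length (default 100).
#' @param lambda_min_ratio ratio of smallest to largest penalty
#'   (default 1e-4).
#' @return Descending numeric vector of penalties.
#' @export
lambda_grid <- function(X, y, penalty_factors = NULL, obs_weights = NULL,
                        n_lambda = 100, lambda_min_ratio = 1e-4,
                        standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  vf <- rep_len(penalty_factors %||% 1, ncol(X))
  w <- normalize_weights(obs_weights, n)
  std <- prep_design(X, y, w, standardize)
  g <- abs(as.numeric(crossprod(w * std$X, std$yc))) / n
  ok <- is.finite(vf) & vf > 0
  if (!any(ok)) stop("no positive finite penalty factors: lambda_max undefined")
  lmax <- max(g[ok] / vf[ok]) * (1 + 1e-9)  # guard against roundoff at the boundary
  if (lmax <= 0) lmax <- .Machine$double.eps
  lmax * exp(seq(0, log(lambda_min_ratio), length.out = n_lambda))
}

#' Weighted LASSO with penalty factors by coordinate descent
#'
#' Solves `min (1/(2n)) sum_i w_i (y_i - b0 - x_i'b)^2 +
#' lambda * sum_j v_j |b_j|` by cyclic coordinate descent with
#' soft-thresholding, warm starts down the penalty grid, and active-set
#' iteration. Columns are standardized internally (weighted mean 0, SD 1) and
#' coefficients returned on the input scale; the intercept is never
#' penalized. Convergence requires both a full sweep with maximum coefficient
#' change below `tol` and a full Karush-Kuhn-Tucker (KKT) check.
#'
#' @inheritParams lambda_grid
#' @param lambda penalty value(s); fit in descending order.
#' @param tol convergence tolerance on the maximum standardized-coefficient
#'   change per sweep (default 1e-8).
#' @param max_iter maximum sweeps per penalty value (default 1e5); hitting it
#'   without satisfying the KKT conditions is an error that reports the
#'   violation.
#' @param kkt_tol KKT residual required at convergence (default 1e-8).
#' @param dev_stop stop the path early once the training R-squared saturates
#'   (exceeds `rsq_max`, or improves by less than `fdev * rsq` per step), the
#'   standard device for not fitting the useless overfit tail of the grid;
#'   the returned path is truncated to the grid points actually solved.
#' @param fdev,rsq_max early-stop controls (defaults 1e-5 and 0.999).
#' @param df_max stop the path once the active set exceeds this size
#'   (default unlimited); saturated tail models cannot be selected by
#'   out-of-fold MSE, so cross-validation bounds this at half the sample
#'   size.
#' @return A list with `beta` (p x n_lambda, input scale), `intercept` (per
#'   lambda), `lambda` (possibly truncated), `kkt` (max residual per lambda),
#'   `iters`, `rsq`, and the normalized weights and penalty factors used.
#' @export
lasso_cd <- function(X, y, lambda, penalty_factors = NULL, obs_weights = NULL,
                     tol = 1e-8, max_iter = 1e5, standardize = TRUE,
                     kkt_tol = 1e-8, dev_stop = FALSE, fdev = 1e-5,
                     rsq_max = 0.999, df_max = Inf) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (any(lambda < 0)) stop("lambda must be >= 0")
  lambda <- sort(lambda, decreasing = TRUE)
  vf <- rep_len(penalty_factors %||% 1, ncol(X))
  if (any(vf < 0)) stop("penalty factors must be >= 0")
  w <- normalize_weights(obs_weights, n)
  std <- prep_design(X, y, w, standardize)

  fit <- cd_lasso_path_cpp(std$X, std$yc, w, vf, lambda,
                           tol, as.integer(max_iter), kkt_tol,
                           dev_stop, fdev, rsq_max, df_max)
  used <- seq_len(fit$n_used)
  if (!all(fit$converged[used]))
    stop(sprintf(
      "coordinate descent did not converge within %d sweeps (max KKT violation %.3e)",
      as.integer(max_iter), max(fit$kkt[used][!fit$converged[used]])))

  beta <- fit$beta[, used, drop = FALSE] / std$scale
  dimnames(beta) <- list(colnames(X), NULL)
  intercept <- std$ybar - as.numeric(crossprod(std$center, beta))
  list(beta = beta, intercept = intercept, lambda = lambda[used],
       kkt = fit$kkt[used], iters = fit$iters[used], rsq = fit$rsq[used],
       penalty_factors = vf, obs_weights = w, standardize = standardize)
}

#' Cross-validated adaptive LASSO
#'
#' The full two-stage procedure used to build a metabolomic severity score:
#' (1) a ridge penalty is chosen by k-fold cross-validation (unless given),
#' (2) ridge coefficients supply adaptive penalty factors
#' `1/|beta_ridge|` (standardized scale, capped), (3) a descending penalty
#' grid is anchored at `lambda_max`, (4) the LASSO path is fit on each
#' training fold and the penalty with lowest mean out-of-fold MSE
#' ("lambda-min") is chosen, and (5) the final model is refit on all data.
#' Passing `penalty_factors = 1` gives the plain (non-adaptive) LASSO under
#' the identical protocol. Deterministic given `seed`.
#'
#' By default (`fold_weights = TRUE`) the adaptive weights used inside each
#' cross-validation fold are re-estimated from that fold's training samples
#' only (one extra ridge solve per fold, at the globally chosen ridge
#' penalty). Weights computed once on the full data — the convention of
#' glmnet-based adaptive-LASSO practice, available as
#' `fold_weights = FALSE` — encode each held-out fold's noise, which biases
#' out-of-fold error downward at small penalties and systematically enlarges
#' the selected set, to the point of erasing the adaptive LASSO's
#' false-positive advantage over the plain LASSO. The final refit always
#' uses the full-data weights.
#'
#' @inheritParams lasso_cd
#' @param folds number of CV folds (default 10; also used for the ridge CV,
#'   on the same partition).
#' @param seed integer seed for the fold partition.
#' @param penalty_factors `NULL` (default) for adaptive factors from ridge;
#'   otherwise fixed per-feature factors.
#' @param ridge_lambda fixed ridge penalty; `NULL` (default) selects it by CV.
#' @param ridge_grid grid for the ridge CV.
#' @param n_lambda,lambda_min_ratio LASSO path grid controls.
#' @param cap penalty-factor cap for near-zero ridge coefficients.
#' @param cv_tol,cv_kkt_tol convergence tolerances for the fold fits, whose
#'   only product is out-of-fold MSE (defaults 1e-5 / 1e-4); the final
#'   returned fit always uses the strict `tol`/KKT criteria.
#' @param df_max path-size bound for fold and final fits (default
#'   `floor(n/2)`): models with more active features than half the sample
#'   size are saturated interpolants the CV-MSE minimum cannot select, so
#'   the path is not extended into them.
#' @param fold_weights re-estimate adaptive weights within each training
#'   fold (default `TRUE`; ignored when `penalty_factors` is supplied).
#' @return An object of class `adalasso_fit`: the penalty grid, coefficient
#'   path, intercepts, CV curve (`cv_mean`, `cv_se`), chosen penalty
#'   (`lambda_min`), selected features and coefficients at the chosen
#'   penalty, penalty factors, ridge penalty, KKT residuals, and the seed.
#' @export
cv_adalasso <- function(X, y, folds = 10, seed = 1, obs_weights = NULL,
                        penalty_factors = NULL, ridge_lambda = NULL,
                        ridge_grid = 10^seq(-4, 3, length.out = 15),
                        n_lambda = 100, lambda_min_ratio = 1e-4,
                        cap = 1e6, standardize = TRUE,
                        tol = 1e-8, max_iter = 1e5,
                        cv_tol = 1e-5, cv_kkt_tol = 1e-4, df_max = NULL,
                        fold_weights = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < folds || folds < 2) stop("need n >= folds >= 2")
  if (var(y) == 0) stop("outcome is constant")
  w <- normalize_weights(obs_weights, n)
  fold_id <- make_folds(n, folds, seed)
  df_max <- df_max %||% max(10, floor(n / 2))

  adaptive <- is.null(penalty_factors)
  if (adaptive) {
    if (is.null(ridge_lambda)) {
      rcv <- ridge_cv(X, y, grid = ridge_grid, obs_weights = w,
                      standardize = standardize, fold_id = fold_id)
      ridge_lambda <- rcv$lambda_ridge
    }
    ridge <- ridge_fit(X, y, ridge_lambda, obs_weights = w,
                       standardize = standardize)
    penalty_factors <- penalty_weights(ridge$beta_std, cap = cap)
  } else {
    penalty_factors <- rep_len(penalty_factors, ncol(X))
  }

  lambda <- lambda_grid(X, y, penalty_factors, w,
                        n_lambda = n_lambda,
                        lambda_min_ratio = lambda_min_ratio,
                        standardize = standardize)

  # Fold fits run at a CV-appropriate tolerance and stop once the training
  # R-squared saturates; the CV curve is restricted to the grid points every
  # fold reached (the saturated tail cannot host the MSE minimum).
  mse <- matrix(NA_real_, length(lambda), max(fold_id))
  n_reached <- length(lambda)
  for (f in seq_len(max(fold_id))) {
    tr <- fold_id != f
    vf_fold <- penalty_factors
    if (adaptive && fold_weights) {
      ridge_f <- ridge_fit(X[tr, , drop = FALSE], y[tr], ridge_lambda,
                           obs_weights = w[tr], standardize = standardize)
      vf_fold <- penalty_weights(ridge_f$beta_std, cap = cap)
    }
    pf <- lasso_cd(X[tr, , drop = FALSE], y[tr], lambda,
                   penalty_factors = vf_fold, obs_weights = w[tr],
                   tol = cv_tol, max_iter = max_iter,
                   standardize = standardize, kkt_tol = cv_kkt_tol,
                   dev_stop = TRUE, df_max = df_max)
    used <- seq_along(pf$lambda)
    n_reached <- min(n_reached, length(used))
    pred <- sweep(X[!tr, , drop = FALSE] %*% pf$beta, 2L, pf$intercept, "+")
    wo <- w[!tr]
    mse[used, f] <- colSums(wo * (y[!tr] - pred)^2) / sum(wo)
  }
  lambda <- lambda[seq_len(n_reached)]
  mse <- mse[seq_len(n_reached), , drop = FALSE]
  cv_mean <- rowMeans(mse)
  cv_se <- apply(mse, 1L, sd) / sqrt(max(fold_id))
  best <- which.min(cv_mean)  # descending grid: first minimum = largest lambda

  # Final fit at full precision down to (at least) the chosen penalty.
  full <- lasso_cd(X, y, lambda, penalty_factors = penalty_factors,
                   obs_weights = w, tol = tol, max_iter = max_iter,
                   standardize = standardize, dev_stop = TRUE,
                   df_max = df_max)
  if (length(full$lambda) < best)
    full <- lasso_cd(X, y, lambda[seq_len(best)],
                     penalty_factors = penalty_factors, obs_weights = w,
                     tol = tol, max_iter = max_iter, standardize = standardize)
  n_path <- length(full$lambda)
  lambda <- lambda[seq_len(n_path)]
  cv_mean <- cv_mean[seq_len(n_path)]
  cv_se <- cv_se[seq_len(n_path)]
  sel <- which(full$beta[, best] != 0)

  structure(list(
    lambda = lambda, beta = full$beta, intercept = full$intercept,
    cv_mean = cv_mean, cv_se = cv_se,
    lambda_min = lambda[best], lambda_min_index = best,
    coefficients = full$beta[sel, best],
    intercept_min = full$intercept[best],
    selected = colnames(X)[sel],
    penalty_factors = penalty_factors, ridge_lambda = ridge_lambda,
    kkt = full$kkt, obs_weights = w, standardize = standardize,
    folds = max(fold_id), seed = seed, n = n
  ), class = "adalasso_fit")
}

#' @export
print.adalasso_fit <- function(x, ...) {
  cat(sprintf(
    "adalasso_fit: %d features selected of %d at lambda = %.4g (%d-fold CV, n = %d)\n",
    length(x$selected), nrow(x$beta), x$lambda_min, x$folds, x$n))
  invisible(x)
}

#' Predict from an adaptive LASSO fit
#'
#' @param object an `adalasso_fit`.
#' @param newx design matrix with the same columns as the training design.
#' @param lambda `"min"` (default) for the CV-chosen penalty, or a grid index.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.adalasso_fit <- function(object, newx, lambda = "min", ...) {
  idx <- if (identical(lambda, "min")) object$lambda_min_index else as.integer(lambda)
  as.numeric(newx %*% object$beta[, idx] + object$intercept[idx])
}

#' KKT optimality residual of a fit
#'
#' Recomputes, on the standardized scale the solver used, the maximum
#' Karush-Kuhn-Tucker violation at the chosen penalty: for zero coefficients
#' the excess of the absolute gradient over `lambda * v_j`; for active ones
#' the distance of the gradient from `lambda * v_j * sign(beta_j)`. A
#' converged fit has a residual at numerical-noise level.
#'
#' @param fit an `adalasso_fit` or the result of [lasso_cd()].
#' @param X,y the data the fit was computed on.
#' @param lambda_index penalty index to check (default: the CV-chosen one for
#'   `adalasso_fit`, the last for a plain path).
#' @return Maximum KKT residual (dimensionless).
#' @export
kkt_check <- function(fit, X, y, lambda_index = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  w <- fit$obs_weights %||% rep(1, n)
  idx <- lambda_index %||% fit$lambda_min_index %||% length(fit$lambda)
  lam <- fit$lambda[idx]
  vf <- fit$penalty_factors
  std <- prep_design(X, y, w, isTRUE(fit$standardize))
  beta_std <- fit$beta[, idx] * std$scale
  r <- std$yc - as.numeric(std$X %*% beta_std)
  g <- as.numeric(crossprod(w * std$X, r)) / n
  viol <- ifelse(beta_std == 0,
                 pmax(0, abs(g) - lam * vf),
                 abs(g - lam * vf * sign(beta_std)))
  max(viol[is.finite(vf)], 0)
}

#' Serialize a fit to JSON / TSV
#'
#' `write_fit_json()` stores feature names, the chosen-penalty coefficients,
#' the grid, CV curve and seed; `write_cv_tsv()` exports the CV curve.
#'
#' @param fit an `adalasso_fit`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    lambda = fit$lambda, lambda_min = fit$lambda_min,
    selected = fit$selected,
    coefficients = as.list(fit$coefficients),
    intercept = fit$intercept_min,
    cv_mean = fit$cv_mean, cv_se = fit$cv_se,
    ridge_lambda = fit$ridge_lambda, folds = fit$folds, seed = fit$seed
  ), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_fit_json
#' @export
write_cv_tsv <- function(fit, path) {
  write.table(
    data.frame(lambda = fit$lambda, cv_mean = fit$cv_mean, cv_se = fit$cv_se),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- internals -------------------------------------------------------------

# Rescale observation weights to sum to n (makes solutions invariant to the
# overall weight scale and puts the loss on the 1/n scale).
normalize_weights <- function(w, n) {
  if (is.null(w)) return(rep(1, n))
  w <- rep_len(w, n)
  if (any(w <= 0) || any(!is.finite(w))) stop("observation weights must be positive")
  w * n / sum(w)
}

# Weighted centering (+ optional scaling) of X and centering of y.
prep_design <- function(X, y, w, standardize) {
  n <- nrow(X)
  if (standardize) {
    std <- weighted_standardize(X, w)
  } else {
    ctr <- as.numeric(crossprod(w, X)) / n
    std <- list(X = sweep(X, 2L, ctr, "-"), center = ctr,
                scale = rep(1, ncol(X)))
  }
  ybar <- sum(w * y) / n
  c(std, list(ybar = ybar, yc = y - ybar))
}
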