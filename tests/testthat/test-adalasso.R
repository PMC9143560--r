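# Shared small fixture: well-conditioned design with 3 real effects.
fixture_xy <- function(n = 100, p = 20, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- as.numeric(X[, 1:3] %*% c(1, -1, 0.5) + rnorm(n))
  list(X = X, y = y)
}

# Design whose columns are mutually orthogonal, orthogonal to the constant
# vector (mean zero), and scaled to SD 1 (divisor n), so the internal
# standardization is the identity and closed forms apply directly.
orthonormal_design <- function(n = 64, p = 6, seed = 3) {
  set.seed(seed)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n))))[, 2:(p + 1), drop = FALSE]
  X <- q * sqrt(n)
  colnames(X) <- paste0("x", 1:p)
  X
}

test_that("ridge regression reduces to OLS at zero penalty", {
  d <- fixture_xy()
  r <- ridge_fit(d$X, d$y, 0)
  o <- lm(d$y ~ d$X)
  expect_equal(unname(r$beta), unname(coef(o)[-1]), tolerance = 1e-10)
  expect_equal(r$intercept, unname(coef(o)[1]), tolerance = 1e-10)
})

test_that("ridge shrinks by 1/(1+lambda) on an orthonormal design", {
  X <- orthonormal_design()
  set.seed(4)
  y <- as.numeric(X %*% rnorm(ncol(X)) + rnorm(nrow(X)))
  ols <- ridge_fit(X, y, 0)$beta
  for (lam in c(0.5, 1, 4))
    expect_equal(ridge_fit(X, y, lam)$beta, ols / (1 + lam), tolerance = 1e-8)
})

test_that("ridge is defined for p > n and errors when it should not be", {
  set.seed(5)
  X <- matrix(rnorm(20 * 50), 20, dimnames = list(NULL, paste0("x", 1:50)))
  y <- rnorm(20)
  r <- ridge_fit(X, y, 1)
  expect_true(all(is.finite(r$beta)))
  expect_error(ridge_fit(X, y, 0), "rank-deficient")
  expect_error(ridge_fit(X, y, -1), ">= 0")
})

test_that("ridge CV is deterministic, honors a singleton grid, and prefers
           heavy shrinkage on pure noise", {
  d <- fixture_xy()
  expect_equal(ridge_cv(d$X, d$y, grid = 2, seed = 1)$lambda_ridge, 2)
  a <- ridge_cv(d$X, d$y, seed = 9)
  b <- ridge_cv(d$X, d$y, seed = 9)
  expect_identical(a$lambda_ridge, b$lambda_ridge)

  grid <- 10^seq(-4, 3, length.out = 15)
  top <- sort(grid, decreasing = TRUE)[1:6]
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    X <- matrix(rnorm(100 * 20), 100, dimnames = list(NULL, paste0("x", 1:20)))
    y <- rnorm(100)
    ridge_cv(X, y, grid = grid, seed = s)$lambda_ridge %in% top
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("penalty weights invert, rectify and cap ridge coefficients", {
  expect_equal(unname(penalty_weights(c(a = 0.5, b = -0.25, c = 1e-12))),
               c(2, 4, 1e6))
  expect_error(penalty_weights(c(1, NA)), "finite")
  expect_error(penalty_weights(c(1, Inf)), "finite")
})

test_that("lambda_max zeroes every penalized coefficient and scales correctly", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(20:60, 1); p <- sample(5:15, 1)
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    vf <- runif(p, 0.3, 3)
    lam <- lambda_grid(X, y, vf, n_lambda = 5)
    f <- lasso_cd(X, y, lam[1], penalty_factors = vf)
    expect_true(all(f$beta == 0))
    expect_equal(lambda_grid(X, y, 2 * vf, n_lambda = 5)[1], lam[1] / 2,
                 tolerance = 1e-12)
  }
  expect_error(lambda_grid(fixture_xy()$X, fixture_xy()$y,
                           penalty_factors = rep(Inf, 20)),
               "penalty factors")
})

test_that("lambda_max equals the absolute weighted covariance for one
           standardized feature", {
  x <- matrix(c(-2, -1, 0, 1, 2), dimnames = list(NULL, "x"))
  y <- c(1, 3, 2, 5, 9)
  lam <- lambda_grid(x, y, n_lambda = 2)
  xs <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(lam[1], abs(mean(xs * (y - mean(y)))), tolerance = 1e-8)
})

test_that("coordinate descent reduces to OLS at lambda zero", {
  d <- fixture_xy(n = 60, p = 8)
  f <- lasso_cd(d$X, d$y, 0)
  o <- lm(d$y ~ d$X)
  expect_equal(unname(f$beta[, 1]), unname(coef(o)[-1]), tolerance = 1e-7)
  expect_equal(f$intercept[1], unname(coef(o)[1]), tolerance = 1e-7)
})

test_that("coordinate descent matches the soft-threshold closed form on an
           orthonormal design", {
  X <- orthonormal_design()
  set.seed(8)
  y <- as.numeric(X %*% c(1.5, -1, 0.6, -0.3, 0.1, 0) + rnorm(nrow(X)))
  vf <- c(1, 1, 2, 0.5, 1, 1)
  ols <- as.numeric(crossprod(X, y - mean(y))) / nrow(X)
  for (lam in c(0.05, 0.2, 0.6)) {
    f <- lasso_cd(X, y, lam, penalty_factors = vf)
    soft <- sign(ols) * pmax(abs(ols) - lam * vf, 0)
    expect_equal(unname(f$beta[, 1]), soft, tolerance = 1e-6)
  }
})

test_that("an unpenalized feature is never thresholded", {
  d <- fixture_xy(n = 80, p = 6)
  vf <- c(0, rep(1, 5))
  f <- lasso_cd(d$X, d$y, 0.8, penalty_factors = vf)
  # at this heavy penalty all penalized features are out, yet x1 stays in
  # at its unpenalized partial solution (KKT: gradient exactly zero)
  expect_true(f$beta[1, 1] != 0)
  expect_true(all(f$beta[-1, 1] == 0))
  expect_lt(kkt_check(c(f, list(lambda_min_index = 1)), d$X, d$y), 1e-8)
})

test_that("solver matches exhaustive sign-pattern and grid-search oracles", {
  set.seed(10)
  for (i in 1:8) {
    n <- 40; p <- sample(3:6, 1)
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
    y <- as.numeric(X %*% (rnorm(p) * rbinom(p, 1, 0.6)) + rnorm(n))
    vf <- runif(p, 0.5, 2)
    lam <- runif(1, 0.05, 0.4)
    f <- lasso_cd(X, y, lam, penalty_factors = vf, standardize = FALSE)
    oracle <- lasso_sign_oracle(X, y, lam, vf)
    expect_equal(unname(f$beta[, 1]), oracle$beta, tolerance = 1e-6)
    expect_equal(f$intercept[1], oracle$intercept, tolerance = 1e-6)
  }
  # dense grid search on 2-feature instances
  for (i in 1:5) {
    X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
    y <- as.numeric(X %*% c(1, -0.5) + rnorm(30))
    f <- lasso_cd(X, y, 0.15, standardize = FALSE)
    g <- lasso_grid_oracle(X, y, 0.15, c(1, 1))
    expect_equal(unname(f$beta[, 1]), g$beta, tolerance = 1e-3)
  }
})

test_that("solution is invariant to the overall observation-weight scale", {
  d <- fixture_xy(n = 50, p = 10, seed = 12)
  w <- runif(50, 0.5, 3)
  lam <- lambda_grid(d$X, d$y, obs_weights = w, n_lambda = 10)
  f1 <- lasso_cd(d$X, d$y, lam, obs_weights = w)
  f2 <- lasso_cd(d$X, d$y, lam, obs_weights = 17 * w)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
})

test_that("solver agrees with glmnet on a shared path", {
  skip_if_not_installed("glmnet")
  d <- fixture_xy(n = 100, p = 20, seed = 14)
  lam <- lambda_grid(d$X, d$y, n_lambda = 20)
  f <- lasso_cd(d$X, d$y, lam)
  g <- glmnet::glmnet(d$X, d$y, lambda = lam, standardize = TRUE,
                      thresh = 1e-12)
  expect_equal(unname(f$beta), unname(as.matrix(g$beta)), tolerance = 1e-5)
  expect_equal(f$intercept, unname(g$a0), tolerance = 1e-5)
})

test_that("cross-validated adaptive LASSO recovers a planted support", {
  set.seed(11)
  n <- 300; p <- 50
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
  beta <- c(rep(1, 5), rep(0, p - 5))
  y <- as.numeric(X %*% beta + rnorm(n))
  fit <- cv_adalasso(X, y, seed = 11)
  expect_true(all(paste0("x", 1:5) %in% fit$selected))
  expect_lt(kkt_check(fit, X, y), 1e-6)
  expect_equal(fit$lambda_min, fit$lambda[which.min(fit$cv_mean)])
  expect_length(fit$cv_mean, length(fit$lambda))

  # same seed, same fit — bitwise
  fit2 <- cv_adalasso(X, y, seed = 11)
  expect_identical(fit[names(fit) != "call"], fit2[names(fit2) != "call"])
})

test_that("cross-validation on pure noise selects almost nothing", {
  set.seed(3)
  X <- matrix(rnorm(200 * 100), 200, dimnames = list(NULL, paste0("x", 1:100)))
  y <- rnorm(200)
  fit <- cv_adalasso(X, y, seed = 3)
  expect_lte(length(fit$selected), 5)
  expect_error(cv_adalasso(X, rep(1, 200), seed = 1), "constant")
})

test_that("path sparsity grows as the penalty decreases", {
  d <- fixture_xy(n = 120, p = 30, seed = 15)
  fit <- cv_adalasso(d$X, d$y, seed = 15)
  nz <- colSums(fit$beta != 0)
  expect_equal(nz[1], 0)                 # empty model at lambda_max
  expect_gte(nz[length(nz)], nz[1])
  expect_equal(fit$beta[fit$selected, fit$lambda_min_index],
               fit$coefficients)
})

test_that("adaptive weighting yields fewer false positives than plain LASSO
           under block correlation", {
  res <- sapply(1:3, function(s) {
    set.seed(s)
    n <- 150; p <- 240; nb <- 12; rho <- 0.5
    block <- sort(rep_len(1:nb, p))
    u <- matrix(rnorm(n * nb), n)
    X <- sqrt(rho) * u[, block] + sqrt(1 - rho) * matrix(rnorm(n * p), n)
    colnames(X) <- paste0("x", 1:p)
    supp <- seq(1, p, by = p %/% 8)[1:8]
    beta <- numeric(p); beta[supp] <- sample(c(-1, 1), 8, TRUE) * 0.5
    y <- as.numeric(X %*% beta + rnorm(n))
    ada <- cv_adalasso(X, y, seed = s)
    pla <- cv_adalasso(X, y, seed = s, penalty_factors = 1)
    c(fp_ada = sum(!ada$selected %in% colnames(X)[supp]),
      fp_pla = sum(!pla$selected %in% colnames(X)[supp]))
  })
  expect_lte(mean(res["fp_ada", ]), mean(res["fp_pla", ]))
})

test_that("KKT check flags a perturbed solution", {
  d <- fixture_xy(n = 80, p = 10, seed = 16)
  fit <- cv_adalasso(d$X, d$y, seed = 16)
  expect_lt(kkt_check(fit, d$X, d$y), 1e-6)
  bad <- fit
  bad$beta[, bad$lambda_min_index] <- bad$beta[, bad$lambda_min_index] + 0.05
  expect_gt(kkt_check(bad, d$X, d$y), 1e-3)

  # all-zero fit at lambda >= lambda_max satisfies the KKT conditions
  lam <- lambda_grid(d$X, d$y, n_lambda = 3)
  f0 <- lasso_cd(d$X, d$y, lam[1])
  expect_lt(kkt_check(c(f0, list(lambda_min_index = 1)), d$X, d$y), 1e-6)
})

test_that("fit artifacts serialize to JSON and TSV", {
  d <- fixture_xy(n = 60, p = 8, seed = 17)
  fit <- cv_adalasso(d$X, d$y, folds = 5, seed = 17)
  js <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(back$selected, fit$selected)
  expect_equal(unlist(back$coefficients), fit$coefficients, tolerance = 0)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_cv_tsv(fit, tsv)
  curve <- read.delim(tsv)
  expect_equal(curve$cv_mean, fit$cv_mean, tolerance = 1e-12)
})
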