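#' Build a metabolomic severity score from a fitted model
#'
#' The metSS is the linear predictor defined by the features selected at the
#' cross-validation-chosen penalty: their coefficients (verbatim, unshrunk
#' further) plus the intercept.
#'
#' @param fit an `adalasso_fit` from [cv_adalasso()].
#' @return An object of class `metss`: `features`, `weights`, `intercept`,
#'   and provenance (`seed`, `lambda_min`, `n_train`).
#' @export
build_metss <- function(fit) {
  stopifnot(inherits(fit, "adalasso_fit"))
  if (length(fit$selected) == 0)
    stop("empty score: no features selected at the chosen penalty")
  structure(list(
    features = fit$selected,
    weights = setNames(as.numeric(fit$coefficients), fit$selected),
    intercept = fit$intercept_min,
    provenance = list(seed = fit$seed, lambda_min = fit$lambda_min,
                      n_train = fit$n)
  ), class = "metss")
}

#' @export
print.metss <- function(x, ...) {
  cat(sprintf("metss: %d features, intercept %.4g\n",
              length(x$features), x$intercept))
  invisible(x)
}

#' Apply a metabolomic severity score to a design matrix
#'
#' Computes `intercept + sum_j w_j * design_ij` per sample. Every score
#' feature must be present in the design; validation designs must be built
#' with the training recipe (see [make_design()]) so columns align.
#'
#' @param score a `metss`.
#' @param design a `harmonized_design` or a bare feature matrix.
#' @return Named numeric vector of per-sample scores (outcome units).
#' @export
apply_metss <- function(score, design) {
  stopifnot(inherits(score, "metss"))
  m <- if (inherits(design, "harmonized_design")) design$design else as.matrix(design)
  absent <- setdiff(score$features, colnames(m))
  if (length(absent))
    stop("score features absent from design: ", paste(absent, collapse = ", "))
  out <- score$intercept + as.numeric(m[, score$features, drop = FALSE] %*% score$weights)
  setNames(out, rownames(m))
}

#' Wherry shrunken adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)`. The `n - p` denominator variant
#' found in parts of the literature is available via `variant`.
#'
#' @param r2 unadjusted R-squared (fraction).
#' @param n sample size; must exceed `p + 1`.
#' @param p number of predictors.
#' @param variant `"n-p-1"` (default, matches mainstream regression output)
#'   or `"n-p"`.
#' @return Adjusted R-squared (fraction; can be negative).
#' @export
wherry_adj_r2 <- function(r2, n, p, variant = c("n-p-1", "n-p")) {
  variant <- match.arg(variant)
  denom <- if (variant == "n-p-1") n - p - 1 else n - p
  if (denom <= 0) stop("adjusted R-squared undefined: n must exceed p + 1")
  1 - (1 - r2) * (n - 1) / denom
}

#' Three-model evaluation of a severity score
#'
#' Fits the three ordinary-least-squares models used to judge a score:
#' clinical covariates only, score only, and score plus covariates. Reports
#' unadjusted and Wherry-adjusted R-squared, MSE (`RSS/n`), and the partial
#' F-test of the combined model against the covariates-only model.
#' Categorical covariates are expanded to indicator contrasts; aliased
#' columns are dropped with a warning.
#'
#' @param y numeric outcome.
#' @param metss_scores per-sample score values (same order as `y`).
#' @param covariates data.frame of clinical covariates.
#' @param variant passed to [wherry_adj_r2()].
#' @return An object of class `model_eval`: a data.frame with one row per
#'   model (`n`, `p`, `r2`, `adj_r2`, `mse`) plus attributes `f_stat`,
#'   `f_p_value` (combined vs covariates-only) and `variant`.
#' @export
eval_models <- function(y, metss_scores, covariates, variant = "n-p-1") {
  stopifnot(length(y) == length(metss_scores), nrow(covariates) == length(y))
  covariates <- droplevels(as.data.frame(covariates))
  dat <- cbind(data.frame(.y = y, .metss = metss_scores), covariates)
  cov_terms <- paste(names(covariates), collapse = " + ")

  fits <- list(
    covariates_only = lm(stats::as.formula(paste(".y ~", cov_terms)), dat),
    metss_only = lm(.y ~ .metss, dat),
    metss_plus_covariates = lm(stats::as.formula(paste(".y ~ .metss +", cov_terms)), dat)
  )
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    cf <- coef(f)
    aliased <- names(cf)[is.na(cf)]
    if (length(aliased))
      warning("aliased columns dropped in ", nm, ": ",
              paste(aliased, collapse = ", "))
    p <- sum(!is.na(cf)) - 1L
    n <- length(f$residuals)
    rss <- sum(f$residuals^2)
    r2 <- summary(f)$r.squared
    data.frame(model = nm, n = n, p = p, r2 = r2,
               adj_r2 = wherry_adj_r2(r2, n, p, variant),
               mse = rss / n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ft <- anova(fits$covariates_only, fits$metss_plus_covariates)
  structure(out,
            f_stat = ft$F[2], f_p_value = ft$`Pr(>F)`[2], variant = variant,
            class = c("model_eval", "data.frame"))
}

#' @export
print.model_eval <- function(x, ...) {
  df <- as.data.frame(x)
  df$adj_r2_pct <- sprintf("%.1f%%", 100 * df$adj_r2)
  print.data.frame(df[, c("model", "n", "p", "adj_r2_pct", "mse")],
                   row.names = FALSE)
  cat(sprintf("combined vs covariates-only: F = %.2f, p = %.3g\n",
              attr(x, "f_stat"), attr(x, "f_p_value")))
  invisible(x)
}

#' Write a three-model evaluation table
#'
#' TSV layout mirrors a train/validation summary table: one row per cohort,
#' adjusted R-squared (percent) and MSE for the three models.
#'
#' @param evals named list of `model_eval` objects (names = cohort labels).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_model_eval_tsv <- function(evals, path) {
  rows <- lapply(names(evals), function(nm) {
    e <- as.data.frame(evals[[nm]])
    stats <- unlist(lapply(c("adj_r2", "mse"), function(col) {
      setNames(e[[col]] * (if (col == "adj_r2") 100 else 1),
               paste(col, e$model, sep = "_"))
    }))
    cbind(data.frame(cohort = nm), as.data.frame(as.list(stats)))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Extreme-quintile observation weights
#'
#' Up-weights the tails of the training outcome distribution: samples in the
#' bottom or top quintile receive weight `factor`, the rest weight 1.
#' Quintile membership is rank-based (ties broken by first occurrence), so
#' exactly `ceiling(n/5)` samples fall in each tail.
#'
#' @param y_train numeric training outcome (n >= 5, non-constant).
#' @param factor tail weight (default 5; 1 recovers the unweighted analysis).
#' @return Numeric weight vector.
#' @export
extreme_quintile_weights <- function(y_train, factor = 5) {
  n <- length(y_train)
  if (n < 5) stop("need at least 5 samples")
  if (var(y_train) == 0) stop("outcome is constant: quintiles undefined")
  r <- rank(y_train, ties.method = "first")
  n_tail <- ceiling(n / 5)
  ifelse(r <= n_tail | r > n - n_tail, factor, 1)
}

#' Observed-versus-predicted calibration line
#'
#' Simple linear regression of the observed outcome on score predictions. A
#' slope below 1 is the shrinkage signature of penalized scores: the highest
#' outcomes are under-predicted and the lowest over-predicted.
#'
#' @param y observed outcome.
#' @param scores predicted values.
#' @return List with `slope`, `intercept`, and `r2`.
#' @export
predicted_vs_observed <- function(y, scores) {
  if (length(y) < 3) stop("need at least 3 samples")
  if (var(scores) == 0) stop("scores have zero variance")
  f <- lm(y ~ scores)
  list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
       r2 = summary(f)$r.squared)
}

#' Serialize a metSS to JSON
#'
#' @param score a `metss`.
#' @param path output file.
#' @return `read_metss_json()` returns the `metss`.
#' @export
write_metss_json <- function(score, path) {
  jsonlite::write_json(list(
    features = score$features, weights = as.list(score$weights),
    intercept = score$intercept, provenance = score$provenance
  ), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_metss_json
#' @export
read_metss_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    features = x$features,
    weights = setNames(as.numeric(unlist(x$weights)), names(x$weights)),
    intercept = x$intercept, provenance = x$provenance
  ), class = "metss")
}
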