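#' Within-batch median normalization
#'
#' Divides each metabolite's intensities, within each profiling batch, by the
#' batch median of that metabolite's observed values, so every
#' (batch, metabolite) stratum has median 1 afterwards. Missing values stay
#' missing. A metabolite entirely missing within a batch is left as-is with a
#' warning; the missingness tiers deal with it downstream.
#'
#' @param mat an [abundance_matrix()].
#' @return A normalized [abundance_matrix()].
#' @export
batch_median_normalize <- function(mat) {
  stopifnot(inherits(mat, "abundance_matrix"))
  v <- mat$values
  n_empty <- 0L
  for (b in unique(mat$batch)) {
    rows <- which(mat$batch == b)
    med <- apply(v[rows, , drop = FALSE], 2L, median, na.rm = TRUE)
    empty <- is.na(med)
    n_empty <- n_empty + sum(empty)
    med[empty] <- 1
    v[rows, ] <- sweep(v[rows, , drop = FALSE], 2L, med, "/")
  }
  if (n_empty > 0)
    warning(n_empty, " (batch, metabolite) strata had no observed values; left unnormalized")
  abundance_matrix(v, mat$batch, mat$metabolite_meta)
}

#' Subject-level quality-control filter
#'
#' Flags gross outlier subjects: metabolite intensities are z-scored across
#' samples (observed values only, population SD), each subject is summarized
#' by the median of its z-scores across metabolites, and subjects whose
#' median lies more than 3 SDs from the cohort mean of these medians are
#' removed.
#'
#' @param mat an [abundance_matrix()] (normally batch-normalized first).
#' @param n_sd removal threshold in SD units (default 3).
#' @return A list with `kept` and `removed` sample id vectors and the
#'   per-sample `median_z` values.
#' @export
subject_qc_filter <- function(mat, n_sd = 3) {
  stopifnot(inherits(mat, "abundance_matrix"))
  v <- mat$values
  if (nrow(v) < 3) stop("subject QC needs at least 3 samples")
  ctr <- colMeans(v, na.rm = TRUE)
  scl <- apply(v, 2L, function(x) {
    x <- x[!is.na(x)]
    sqrt(mean((x - mean(x))^2))
  })
  scl[!is.finite(scl) | scl == 0] <- 1
  z <- sweep(sweep(v, 2L, ctr, "-"), 2L, scl, "/")
  med_z <- apply(z, 1L, median, na.rm = TRUE)
  mu <- mean(med_z)
  sdev <- sqrt(mean((med_z - mu)^2))
  out <- if (sdev == 0) rep(FALSE, length(med_z)) else abs(med_z - mu) > n_sd * sdev
  list(kept = rownames(v)[!out], removed = rownames(v)[out], median_z = med_z)
}

#' Missingness tiers
#'
#' Classifies each metabolite by its observed missing fraction: `IMPUTE`
#' (< 20%, retained as a continuous feature with kNN imputation),
#' `INDICATOR` (20-80% inclusive, dichotomized to a present/absent 0/1
#' feature), `DROP` (> 80%, excluded).
#'
#' @param mat an [abundance_matrix()].
#' @param thresholds lower/upper tier boundaries (default `c(0.20, 0.80)`).
#' @return A data.frame of class `feature_categories` with columns
#'   `metabolite`, `missing_frac`, `category`.
#' @export
categorize_missingness <- function(mat, thresholds = c(0.20, 0.80)) {
  stopifnot(inherits(mat, "abundance_matrix"))
  frac <- colMeans(is.na(mat$values))
  cat <- ifelse(frac < thresholds[1], "IMPUTE",
                ifelse(frac <= thresholds[2], "INDICATOR", "DROP"))
  structure(
    data.frame(metabolite = colnames(mat$values), missing_frac = frac,
               category = cat, row.names = NULL, stringsAsFactors = FALSE),
    class = c("feature_categories", "data.frame")
  )
}

#' Harmonize feature handling across two cohorts
#'
#' Restricted to the metabolites present in both cohorts, a metabolite is
#' kept as a continuous feature only if it is in the `IMPUTE` tier in both
#' cohorts, and as a present/absent indicator only if it is `INDICATOR` in
#' both; metabolites with discordant tiers, or `DROP` in either cohort, are
#' excluded.
#'
#' @param cat_a,cat_b [categorize_missingness()] results for the two cohorts.
#' @return A data.frame of class `harmonization_plan` with columns
#'   `metabolite` and `feature_type` (`"continuous"` or `"indicator"`);
#'   attribute `counts` tallies the harmonization arithmetic.
#' @export
harmonize <- function(cat_a, cat_b) {
  common <- intersect(cat_a$metabolite, cat_b$metabolite)
  if (length(common) == 0) stop("no metabolites shared between cohorts")
  a <- setNames(cat_a$category, cat_a$metabolite)[common]
  b <- setNames(cat_b$category, cat_b$metabolite)[common]
  type <- ifelse(a == "IMPUTE" & b == "IMPUTE", "continuous",
                 ifelse(a == "INDICATOR" & b == "INDICATOR", "indicator", NA))
  plan <- data.frame(metabolite = common, feature_type = type,
                     stringsAsFactors = FALSE)
  counts <- c(common = length(common),
              continuous = sum(type == "continuous", na.rm = TRUE),
              indicator = sum(type == "indicator", na.rm = TRUE),
              dropped_either = sum(a == "DROP" | b == "DROP"),
              discordant = sum(is.na(type) & a != "DROP" & b != "DROP"))
  plan <- plan[!is.na(plan$feature_type), , drop = FALSE]
  rownames(plan) <- NULL
  structure(plan, counts = counts,
            class = c("harmonization_plan", "data.frame"))
}

#' k-nearest-neighbour imputation
#'
#' Fills each missing cell with the unweighted mean of the feature's values
#' among the k nearest samples. Sample-to-sample distance is Euclidean over
#' the features observed in both samples, scaled by the number of shared
#' features (root-mean-square difference), so samples with different
#' missingness patterns remain comparable. Only neighbours with the target
#' feature observed are eligible; if fewer than k exist, all are used; if
#' none exists with a finite distance, the feature mean is used.
#'
#' @param x numeric matrix (samples x features) with `NA`s; typically
#'   log-scale values.
#' @param k neighbour count (default 10), clamped to the available samples.
#' @return The completed matrix.
#' @export
knn_impute <- function(x, k = 10) {
  x <- as.matrix(x)
  if (k < 1) stop("k must be >= 1")
  obs_count <- colSums(!is.na(x))
  if (any(obs_count == 0))
    stop("feature(s) with no observed values: ",
         paste(colnames(x)[obs_count == 0], collapse = ", "))
  if (!anyNA(x)) return(x)

  O <- !is.na(x)
  M <- x; M[!O] <- 0
  A <- M^2
  Om <- O * 1
  # Sum over shared features of (x_a - x_b)^2, and shared-feature counts.
  ss <- A %*% t(Om) + Om %*% t(A) - 2 * M %*% t(M)
  shared <- Om %*% t(Om)
  D <- sqrt(pmax(ss, 0) / ifelse(shared > 0, shared, NA))
  D[shared == 0] <- Inf
  diag(D) <- Inf

  feat_mean <- colMeans(x, na.rm = TRUE)
  out <- x
  for (i in which(rowSums(!O) > 0)) {
    ord <- order(D[i, ])
    ord <- ord[is.finite(D[i, ord])]
    for (j in which(!O[i, ])) {
      donors <- ord[O[ord, j]]
      if (length(donors) == 0) {
        out[i, j] <- feat_mean[j]
      } else {
        use <- donors[seq_len(min(k, length(donors)))]
        out[i, j] <- mean(x[use, j])
      }
    }
  }
  out
}

#' Build the model-ready design for one cohort
#'
#' Applies the full feature preparation defined by a harmonization plan:
#' within-batch median normalization, natural-log transform of continuous
#' features (nonpositive normalized values are treated as missing before
#' imputation), kNN imputation on the log scale, and 0/1 present/absent
#' columns for indicator features. Columns are named `log_<id>` /
#' `det_<id>` and ordered by feature name so two cohorts built from the same
#' plan align exactly. When `recipe` (from a previous, typically training,
#' run) is supplied, its plan and parameters are reused so a validation
#' cohort is prepared identically.
#'
#' @param mat a raw [abundance_matrix()] (after any subject QC).
#' @param plan a [harmonize()] plan; ignored when `recipe` is given.
#' @param recipe a recipe from a previous `make_design()` call.
#' @param k neighbour count for imputation.
#' @return A list of class `harmonized_design`: `design` (numeric matrix,
#'   samples x features, no missing values) and `recipe`.
#' @export
make_design <- function(mat, plan = NULL, recipe = NULL, k = 10) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (!is.null(recipe)) {
    plan <- recipe$plan
    k <- recipe$k
  }
  if (is.null(plan)) stop("either a harmonization plan or a recipe is required")
  missing_ids <- setdiff(plan$metabolite, colnames(mat$values))
  if (length(missing_ids))
    stop("plan metabolites absent from matrix: ",
         paste(head(missing_ids, 5), collapse = ", "))

  norm <- batch_median_normalize(mat)
  cont_ids <- plan$metabolite[plan$feature_type == "continuous"]
  ind_ids <- plan$metabolite[plan$feature_type == "indicator"]

  blocks <- list()
  if (length(cont_ids)) {
    lv <- norm$values[, cont_ids, drop = FALSE]
    nonpos <- !is.na(lv) & lv <= 0
    if (any(nonpos)) {
      message(sum(nonpos), " nonpositive normalized values treated as missing before log")
      lv[nonpos] <- NA
    }
    lv <- log(lv)
    lv <- knn_impute(lv, k = k)
    colnames(lv) <- paste0("log_", cont_ids)
    blocks$cont <- lv
  }
  if (length(ind_ids)) {
    iv <- 1 - is.na(mat$values[, ind_ids, drop = FALSE])
    colnames(iv) <- paste0("det_", ind_ids)
    blocks$ind <- iv
  }
  design <- do.call(cbind, unname(blocks))
  design <- design[, order(colnames(design)), drop = FALSE]

  batch_medians <- lapply(split(seq_len(nrow(mat$values)), mat$batch),
                          function(rows) apply(mat$values[rows, , drop = FALSE],
                                               2L, median, na.rm = TRUE))
  structure(
    list(design = design,
         recipe = list(plan = plan, k = k, log_base = "natural",
                       columns = colnames(design),
                       batch_medians = batch_medians)),
    class = "harmonized_design"
  )
}

#' @export
print.harmonized_design <- function(x, ...) {
  tt <- table(x$recipe$plan$feature_type)
  cat(sprintf("harmonized_design: %d samples x %d features (%s continuous, %s indicator)\n",
              nrow(x$design), ncol(x$design),
              tt["continuous"] %||% 0, tt["indicator"] %||% 0))
  invisible(x)
}

#' Table-1-style cohort comparison
#'
#' Compares each shared variable between two clinical tables: two-sample
#' t-tests for numeric variables (pooled variance by default), and for
#' categorical variables a chi-squared test (continuity-corrected for 2x2
#' tables) or Fisher's exact test when any expected cell count is below 5.
#'
#' @param clin_a,clin_b clinical data.frames.
#' @param variables variables to compare; defaults to all shared columns
#'   except `sample_id`.
#' @param pooled_var logical; pooled-variance t-test (default) or Welch.
#' @return A data.frame with one row per variable: per-cohort summary
#'   (`mean (sd)` or counts), test used and p-value.
#' @export
cohort_compare <- function(clin_a, clin_b, variables = NULL, pooled_var = TRUE) {
  if (is.null(variables))
    variables <- setdiff(intersect(names(clin_a), names(clin_b)), "sample_id")
  rows <- lapply(variables, function(v) {
    if (!v %in% names(clin_a) || !v %in% names(clin_b)) {
      warning("variable '", v, "' missing in one cohort; skipped")
      return(NULL)
    }
    a <- clin_a[[v]]; b <- clin_b[[v]]
    if (is.numeric(a) && is.numeric(b)) {
      tt <- t.test(a, b, var.equal = pooled_var)
      data.frame(
        variable = v,
        summary_a = sprintf("%.2f (%.2f)", mean(a, na.rm = TRUE), sd(a, na.rm = TRUE)),
        summary_b = sprintf("%.2f (%.2f)", mean(b, na.rm = TRUE), sd(b, na.rm = TRUE)),
        test = if (pooled_var) "t (pooled)" else "t (Welch)",
        p_value = tt$p.value, stringsAsFactors = FALSE
      )
    } else {
      lev <- sort(unique(c(as.character(a), as.character(b))))
      tab <- rbind(table(factor(a, lev)), table(factor(b, lev)))
      ct <- suppressWarnings(chisq.test(tab, correct = nrow(tab) == 2 && ncol(tab) == 2))
      if (any(ct$expected < 5)) {
        ft <- fisher.test(tab)
        test <- "Fisher"; p <- ft$p.value
      } else {
        test <- if (ncol(tab) == 2) "chi-squared (corrected)" else "chi-squared"
        p <- ct$p.value
      }
      data.frame(
        variable = v,
        summary_a = paste(sprintf("%s:%d", lev, tab[1, ]), collapse = " "),
        summary_b = paste(sprintf("%s:%d", lev, tab[2, ]), collapse = " "),
        test = test, p_value = p, stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
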