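test_that("batch median normalization makes every stratum's median 1", {
  m <- make_abund(matrix(c(2, 4, 8), 3, 1))
  out <- batch_median_normalize(m)
  expect_equal(as.numeric(out$values), c(0.5, 1, 2))

  # two batches with very different scales end up comparable
  v <- rbind(matrix(10 * c(1, 2, 3), 3, 2), matrix(100 * c(1, 2, 3), 3, 2))
  m2 <- make_abund(v, batch = rep(c("A", "B"), each = 3))
  out2 <- batch_median_normalize(m2)
  for (b in c("A", "B"))
    expect_equal(unname(apply(out2$values[out2$batch == b, ], 2, median)),
                 c(1, 1))

  # an all-missing metabolite passes through untouched, with a warning
  v3 <- cbind(c(1, 2, 3), NA_real_)
  expect_warning(out3 <- batch_median_normalize(make_abund(v3)), "strata")
  expect_true(all(is.na(out3$values[, 2])))
})

test_that("missing values stay missing through normalization", {
  v <- matrix(c(1, NA, 3, 4, 5, NA), 3, 2)
  out <- batch_median_normalize(make_abund(v))
  expect_identical(unname(is.na(out$values)), is.na(v))
})

test_that("subject QC removes gross outliers and is idempotent", {
  set.seed(2)
  v <- matrix(rlnorm(51 * 30, meanlog = 2), 51, 30)
  v[51, ] <- v[51, ] * exp(10)  # one subject shifted +10 SD on the log scale
  m <- make_abund(v)
  qc <- subject_qc_filter(batch_median_normalize(m))
  expect_identical(qc$removed, "s51")

  kept <- subset_samples(m, qc$kept)
  qc2 <- subject_qc_filter(batch_median_normalize(kept))
  expect_length(qc2$removed, 0)
})

test_that("subject QC keeps everyone when all subjects are identical", {
  v <- matrix(rep(c(1, 2, 3, 4, 5), each = 6), 6, 5)
  qc <- subject_qc_filter(make_abund(v))
  expect_length(qc$removed, 0)
  expect_error(subject_qc_filter(make_abund(v[1:2, ])), "3 samples")
})

test_that("missingness tier boundaries follow the 20/80 rule inclusively", {
  n <- 10000
  fracs <- c(0, 0.19990, 0.2, 0.5, 0.8, 0.80010, 0.85, 1)
  v <- sapply(fracs, function(f) {
    x <- rlnorm(n)
    x[seq_len(round(f * n))] <- NA
    x
  })
  cats <- categorize_missingness(make_abund(v))
  expect_equal(cats$category,
               c("IMPUTE", "IMPUTE", "INDICATOR", "INDICATOR", "INDICATOR",
                 "DROP", "DROP", "DROP"))
  expect_equal(cats$missing_frac, fracs, tolerance = 1e-9)
})

test_that("harmonization keeps concordant tiers and drops the rest", {
  mk <- function(cats) {
    structure(data.frame(metabolite = paste0("m", seq_along(cats)),
                         missing_frac = 0, category = cats,
                         stringsAsFactors = FALSE),
              class = c("feature_categories", "data.frame"))
  }
  a <- mk(c("IMPUTE", "IMPUTE", "INDICATOR", "INDICATOR", "DROP", "IMPUTE"))
  b <- mk(c("IMPUTE", "INDICATOR", "INDICATOR", "DROP", "IMPUTE", "DROP"))
  plan <- harmonize(a, b)
  expect_equal(plan$metabolite, c("m1", "m3"))
  expect_equal(plan$feature_type, c("continuous", "indicator"))
  cnt <- attr(plan, "counts")
  expect_equal(unname(cnt["continuous"] + cnt["indicator"]), nrow(plan))

  # retained-count identity on random tier assignments
  set.seed(4)
  for (i in 1:20) {
    ca <- mk(sample(c("IMPUTE", "INDICATOR", "DROP"), 50, TRUE))
    cb <- mk(sample(c("IMPUTE", "INDICATOR", "DROP"), 50, TRUE))
    pl <- harmonize(ca, cb)
    both_imp <- sum(ca$category == "IMPUTE" & cb$category == "IMPUTE")
    both_ind <- sum(ca$category == "INDICATOR" & cb$category == "INDICATOR")
    expect_equal(nrow(pl), both_imp + both_ind)
  }
  expect_error(harmonize(mk("IMPUTE"), mk("IMPUTE")[0, ]), "shared")
})

test_that("kNN imputation matches the brute-force oracle", {
  # hand-checkable 4x3 instance with one missing cell
  x <- rbind(c(1, 2, 3), c(1.1, 2.1, NA), c(5, 6, 7), c(1.05, 2.05, 3.2))
  colnames(x) <- paste0("f", 1:3)
  out <- knn_impute(x, k = 2)
  # rows 1 and 4 are the two nearest neighbours of row 2
  expect_equal(unname(out[2, 3]), mean(c(3, 3.2)))
  expect_identical(out[!is.na(x)], x[!is.na(x)])

  # oracle equivalence on random small instances with varied missingness
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:8, 1); p <- sample(3:6, 1); k <- sample(1:4, 1)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    holes <- sample(n * p, ceiling(0.2 * n * p))
    x[holes] <- NA
    x[, colSums(!is.na(x)) == 0] <- rnorm(n)  # keep every feature observed
    expect_equal(knn_impute(x, k), brute_knn_impute(x, k), tolerance = 1e-12)
  }
})

test_that("kNN imputation handles edge conditions", {
  x <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, paste0("f", 1:3)))
  expect_identical(knn_impute(x, 10), x)       # complete input unchanged
  x2 <- x; x2[1, 1] <- NA
  expect_equal(knn_impute(x2, k = 10), knn_impute(x2, k = 3))  # k clamped
  x3 <- x; x3[, 2] <- NA
  expect_error(knn_impute(x3), "no observed values")
  expect_error(knn_impute(x2, k = 0), "k must be")
})

test_that("design construction follows the recipe and is reproducible", {
  set.seed(9)
  pair <- generate_cohort_pair(synth_config(
    n_train = 60, n_valid = 60, p_metabolites = 40, n_blocks = 4,
    n_true_effects = 3, effect_sd = 0.35, seed = 13))
  plan <- harmonize(categorize_missingness(pair$train$abundance),
                    categorize_missingness(pair$valid$abundance))
  d1 <- suppressMessages(suppressWarnings(make_design(pair$train$abundance, plan)))
  d2 <- suppressMessages(suppressWarnings(
    make_design(pair$train$abundance, recipe = d1$recipe)))
  expect_identical(d1$design, d2$design)   # recipe reapplication is exact

  expect_false(anyNA(d1$design))
  ind_cols <- grep("^det_", colnames(d1$design), value = TRUE)
  if (length(ind_cols))
    expect_true(all(d1$design[, ind_cols] %in% c(0, 1)))
  expect_identical(colnames(d1$design), sort(colnames(d1$design)))

  # indicator column is exactly the observed/missing pattern
  if (length(ind_cols)) {
    met <- sub("^det_", "", ind_cols[1])
    expect_equal(unname(d1$design[, ind_cols[1]]),
                 as.numeric(!is.na(pair$train$abundance$values[, met])))
  }
})

test_that("a unit normalized intensity maps to log value zero", {
  v <- matrix(c(2, 4, 8, 1, 1, 1), 3, 2)
  plan <- structure(data.frame(metabolite = c("m01", "m02"),
                               feature_type = "continuous",
                               stringsAsFactors = FALSE),
                    class = c("harmonization_plan", "data.frame"))
  d <- make_design(make_abund(v), plan)
  expect_equal(unname(d$design[2, "log_m01"]), 0)  # the median sample
  expect_equal(unname(d$design[, "log_m02"]), c(0, 0, 0))
})

test_that("cohort comparison reproduces the printed sex-count p-value", {
  clin_a <- data.frame(sex = rep(c("male", "female"), c(349, 299)))
  clin_b <- data.frame(sex = rep(c("male", "female"), c(562, 558)))
  row <- cohort_compare(clin_a, clin_b, "sex")
  expect_equal(round(row$p_value, 3), 0.149)
  expect_match(row$test, "chi-squared")
})

test_that("cohort comparison picks the right test per variable type", {
  set.seed(1)
  a <- data.frame(age = rnorm(50, 60), grp = rep(c("x", "y"), 25))
  rows <- cohort_compare(a, a)
  expect_equal(rows$p_value[rows$variable == "age"], 1)
  expect_equal(rows$p_value[rows$variable == "grp"], 1)

  # sparse 2x2 table falls back to Fisher's exact test
  fa <- data.frame(g = rep(c("a", "b"), c(5, 0)))
  fb <- data.frame(g = rep(c("a", "b"), c(0, 5)))
  row <- suppressWarnings(cohort_compare(fa, fb, "g"))
  expect_equal(row$test, "Fisher")
  expect_equal(row$p_value, 0.007936508, tolerance = 1e-7)

  expect_warning(out <- cohort_compare(a, a[, "age", drop = FALSE],
                                       c("age", "grp")), "skipped")
  expect_equal(nrow(out), 1)
})
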