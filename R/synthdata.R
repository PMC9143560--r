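#' Configuration for the synthetic two-cohort generator
#'
#' Defines the generative model used throughout the package's validation:
#' two cohorts of ever-smoker-like subjects with clinical covariates, a
#' latent sample-by-metabolite matrix of log-abundances with block
#' (equicorrelated) correlation, a continuous outcome driven by a sparse set
#' of metabolite effects plus covariates plus Gaussian noise, multiplicative
#' per-batch intensity effects, and abundance-dependent (left-censored)
#' missingness that produces the three missingness tiers used downstream
#' (fully quantified, present/absent, excluded).
#'
#' Defaults mirror the study design the package emulates: a training cohort
#' of 650 and a validation cohort of 1120 subjects, 762 metabolites in
#' blocks of ~20 with within-block correlation 0.5, 25 true effects, and a
#' metabolite contribution of about 60% of outcome variance. When `noise_sd`
#' is `NULL` it is derived in closed form so that the generative metabolite
#' R-squared equals `target_metabolite_r2`.
#'
#' @param n_train,n_valid cohort sizes.
#' @param p_metabolites number of metabolites.
#' @param n_blocks number of correlation blocks (equal sizes up to rounding).
#' @param within_block_corr equicorrelation within a block, in `[0, 1)`.
#' @param n_true_effects number of metabolites with nonzero outcome effects.
#' @param effect_sd absolute effect size (outcome units per SD of latent
#'   log-abundance); all true effects have magnitude `effect_sd`, random sign.
#' @param noise_sd residual SD of the outcome (outcome units); if `NULL`,
#'   derived from `target_metabolite_r2`.
#' @param target_metabolite_r2 fraction of outcome variance contributed by
#'   metabolites; used only when `noise_sd` is `NULL`.
#' @param batch_count profiling batches per cohort.
#' @param batch_effect_sd SD of per-(batch, metabolite) log-scale shifts.
#' @param tier_shares length-2 fractions of metabolites assigned to the
#'   fully-quantified (<20% missing) and present/absent (20-80%) tiers; the
#'   remainder is assigned to the excluded (>80%) tier.
#' @param tier_flip_prob per-cohort probability that a metabolite's tier is
#'   flipped to an adjacent tier, creating cross-cohort discordance.
#' @param covariate_effects named list of outcome effects for the clinical
#'   covariates (`sex_male`, `height`, `age`, `bmi`, `pack_years`,
#'   `smoking_current`); pass zeros for a covariate-free outcome.
#' @param outcomes outcome names to generate: `"fev1"` (liters) and/or
#'   `"density"` (lung-density-like, g/L).
#' @param cohort_shift logical; if `TRUE` (default) the validation cohort has
#'   shifted covariate distributions (older, fewer current smokers, less
#'   diverse, different site labels), mirroring real paired cohorts.
#' @param keep_latent attach the latent log-abundance matrices to the truth
#'   record (diagnostics/testing only; default `FALSE`).
#' @param seed integer seed; all generator randomness flows from it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_train = 650, n_valid = 1120, p_metabolites = 762,
                         n_blocks = 38, within_block_corr = 0.5,
                         n_true_effects = 25, effect_sd = 0.14,
                         noise_sd = NULL, target_metabolite_r2 = 0.6,
                         batch_count = 4, batch_effect_sd = 0.3,
                         tier_shares = c(0.72, 0.12), tier_flip_prob = 0.07,
                         covariate_effects = NULL, outcomes = "fev1",
                         cohort_shift = TRUE, keep_latent = FALSE, seed = 1) {
  counts <- c(n_train = n_train, n_valid = n_valid,
              p_metabolites = p_metabolites, n_blocks = n_blocks,
              batch_count = batch_count)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be positive integers")
  if (n_true_effects < 0 || n_true_effects > p_metabolites)
    stop("n_true_effects must be in [0, p_metabolites]")
  if (within_block_corr < 0 || within_block_corr >= 1)
    stop("within_block_corr must be in [0, 1)")
  if (length(tier_shares) != 2 || any(tier_shares < 0) || sum(tier_shares) > 1)
    stop("tier_shares must be two nonnegative fractions summing to <= 1")
  if (!all(outcomes %in% c("fev1", "density")))
    stop("outcomes must be a subset of c('fev1', 'density')")

  eff <- list(sex_male = 0.30, height = 0.022, age = -0.015, bmi = -0.008,
              pack_years = -0.002, smoking_current = -0.08)
  if (!is.null(covariate_effects)) {
    bad <- setdiff(names(covariate_effects), names(eff))
    if (length(bad)) stop("unknown covariate effects: ", paste(bad, collapse = ", "))
    eff[names(covariate_effects)] <- covariate_effects
  }

  cfg <- list(n_train = n_train, n_valid = n_valid,
              p_metabolites = p_metabolites, n_blocks = n_blocks,
              within_block_corr = within_block_corr,
              n_true_effects = n_true_effects, effect_sd = effect_sd,
              noise_sd = noise_sd, target_metabolite_r2 = target_metabolite_r2,
              batch_count = batch_count, batch_effect_sd = batch_effect_sd,
              tier_shares = tier_shares, tier_flip_prob = tier_flip_prob,
              covariate_effects = eff, outcomes = outcomes,
              cohort_shift = cohort_shift, keep_latent = keep_latent,
              seed = as.integer(seed))

  if (is.null(cfg$noise_sd)) {
    sig <- n_true_effects * effect_sd^2  # true effects occupy distinct blocks
    cv <- covariate_variance(eff)
    r2 <- target_metabolite_r2
    if (sig <= 0 || r2 <= 0 || r2 >= 1) {
      cfg$noise_sd <- 0.45
    } else {
      nv <- sig / r2 - sig - cv
      if (nv <= 0)
        stop("target_metabolite_r2 unattainable given covariate effects")
      cfg$noise_sd <- sqrt(nv)
    }
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  structure(cfg, class = "synth_config")
}

# Closed-form variance of the covariate contribution to the outcome under the
# training-cohort covariate distributions (sex ~ Bern(.52); height = 161.5 +
# 13*male + N(0, 6.5^2); age ~ N(63, 9^2); bmi ~ N(28.5, 5.5^2); pack-years =
# max(0, N(45, 30^2)), zero-censored moments used exactly; current smoking ~
# Bern(.335)).
covariate_variance <- function(eff) {
  p_m <- 0.52; v_sex <- p_m * (1 - p_m)
  v_height <- 13^2 * v_sex + 6.5^2
  cov_sh <- 13 * v_sex
  mu <- 45; sg <- 30; a <- mu / sg
  ey <- mu * stats::pnorm(a) + sg * stats::dnorm(a)
  ey2 <- (mu^2 + sg^2) * stats::pnorm(a) + mu * sg * stats::dnorm(a)
  v_pack <- ey2 - ey^2
  p_c <- 0.335
  eff$sex_male^2 * v_sex + eff$height^2 * v_height +
    2 * eff$sex_male * eff$height * cov_sh +
    eff$age^2 * 81 + eff$bmi^2 * 5.5^2 + eff$pack_years^2 * v_pack +
    eff$smoking_current^2 * p_c * (1 - p_c)
}

# Clinical covariates for one cohort. `shift` applies the validation-cohort
# distribution differences (older, fewer current smokers, different sites).
gen_clinical <- function(n, prefix, shift) {
  sex <- ifelse(runif(n) < (if (shift) 0.50 else 0.52), "male", "female")
  height <- 161.5 + 13 * (sex == "male") + rnorm(n, 0, 6.5)
  age <- rnorm(n, if (shift) 67 else 63, 9)
  bmi <- rnorm(n, 28.5, 5.5)
  pack <- pmax(0, rnorm(n, if (shift) 42 else 45, if (shift) 26 else 30))
  smoke_p <- if (shift) c(0.06, 0.70, 0.24) else c(0.09, 0.575, 0.335)
  smoking <- sample(c("never", "former", "current"), n, TRUE, smoke_p)
  race_p <- if (shift) c(0.915, 0.085, 0) else c(0.72, 0.19, 0.09)
  race <- sample(c("nhw", "black", "other"), n, TRUE, race_p)
  n_sites <- if (shift) 4L else 3L
  site <- sample(paste0(prefix, "S", seq_len(n_sites)), n, TRUE)
  data.frame(
    sample_id = sprintf("%s%04d", prefix, seq_len(n)),
    sex = sex, age = age, height = height, race = race, bmi = bmi,
    smoking_status = smoking, pack_years = pack, site = site,
    stringsAsFactors = FALSE
  )
}

covariate_contribution <- function(clin, eff) {
  eff$sex_male * (clin$sex == "male") +
    eff$height * (clin$height - 168) +
    eff$age * (clin$age - 65) +
    eff$bmi * (clin$bmi - 28.5) +
    eff$pack_years * (clin$pack_years - 44) +
    eff$smoking_current * (clin$smoking_status == "current")
}

# Latent log-abundances: block-equicorrelated Gaussian, unit SD per
# metabolite, metabolite-specific means.
gen_latent <- function(n, mu, block_of, rho) {
  p <- length(mu)
  u <- matrix(rnorm(n * max(block_of)), n)
  e <- matrix(rnorm(n * p), n)
  z <- sqrt(rho) * u[, block_of, drop = FALSE] + sqrt(1 - rho) * e
  sweep(z, 2L, mu, "+")
}

#' Generate a paired synthetic training/validation cohort with known truth
#'
#' Draws two cohorts from the generative model in [synth_config()]: latent
#' block-correlated log-abundances, outcome(s) from sparse metabolite effects
#' plus clinical covariates plus noise, observed intensities
#' `exp(log-abundance + batch shift)`, and left-censored missingness by tier.
#' The same metabolite truth (support, coefficients, tier assignment of
#' true-effect metabolites) underlies both cohorts; covariate distributions
#' differ between cohorts when `cohort_shift` is on. True-effect metabolites
#' are always placed in the fully-quantified tier of both cohorts, one per
#' correlation block.
#'
#' @param config a [synth_config()].
#' @return A list with elements `train` and `valid` (each a list with
#'   `abundance`, an [abundance_matrix()], and `clinical`, a data.frame that
#'   includes the outcome column(s)), and `truth`: per outcome, the true
#'   support, coefficients, covariate effects and generative metabolite
#'   R-squared, plus the per-metabolite censoring quantiles used.
#' @export
generate_cohort_pair <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    p <- config$p_metabolites
    met_ids <- sprintf("met%04d", seq_len(p))
    block_of <- sort(rep_len(seq_len(config$n_blocks), p))
    mu <- runif(p, 5, 11)

    # One true effect per block (sampled without replacement over blocks).
    supp_idx <- integer(0)
    if (config$n_true_effects > 0) {
      blocks <- sample(seq_len(config$n_blocks),
                       min(config$n_true_effects, config$n_blocks))
      supp_idx <- vapply(blocks, function(b) {
        cand <- which(block_of == b)
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
      extra <- config$n_true_effects - length(supp_idx)
      if (extra > 0)
        supp_idx <- c(supp_idx, sample(setdiff(seq_len(p), supp_idx), extra))
      supp_idx <- sort(supp_idx)
    }

    truth <- list(metabolite_ids = met_ids, block = block_of)
    betas <- list()
    for (oc in config$outcomes) {
      scale <- if (oc == "density") 24 / 0.9 else 1
      b <- numeric(p)
      if (length(supp_idx))
        b[supp_idx] <- sample(c(-1, 1), length(supp_idx), TRUE) *
          config$effect_sd * scale
      betas[[oc]] <- b
    }

    # Tier assignment: shared base tier per metabolite, per-cohort flips.
    shares <- c(config$tier_shares, 1 - sum(config$tier_shares))
    base_tier <- sample(c("impute", "indicator", "drop"), p, TRUE, shares)
    base_tier[supp_idx] <- "impute"
    flip <- function(tier) {
      do_flip <- runif(p) < config$tier_flip_prob
      do_flip[supp_idx] <- FALSE
      out <- tier
      out[do_flip & tier == "impute"] <- "indicator"
      out[do_flip & tier == "indicator"] <-
        sample(c("impute", "drop"), sum(do_flip & tier == "indicator"), TRUE)
      out[do_flip & tier == "drop"] <- "indicator"
      out
    }
    tier_q <- function(tier) {
      q <- numeric(p)
      q[tier == "impute"] <- runif(sum(tier == "impute"), 0.005, 0.15)
      q[tier == "indicator"] <- runif(sum(tier == "indicator"), 0.25, 0.75)
      q[tier == "drop"] <- runif(sum(tier == "drop"), 0.85, 0.995)
      q
    }

    gen_cohort <- function(n, prefix, shift) {
      clin <- gen_clinical(n, prefix, shift)
      z <- gen_latent(n, mu, block_of, config$within_block_corr)
      for (oc in config$outcomes) {
        scale <- if (oc == "density") 24 / 0.9 else 1
        b0 <- if (oc == "density") 84 else 2.3
        clin[[oc]] <- b0 + scale * covariate_contribution(clin, config$covariate_effects) +
          sweep(z, 2L, mu, "-") %*% betas[[oc]] +
          rnorm(n, 0, config$noise_sd * scale)
        clin[[oc]] <- as.numeric(clin[[oc]])
      }
      batch <- sample(paste0(prefix, "B", seq_len(config$batch_count)), n, TRUE)
      shifts <- matrix(rnorm(config$batch_count * p, 0, config$batch_effect_sd),
                       config$batch_count, p,
                       dimnames = list(paste0(prefix, "B", seq_len(config$batch_count)), NULL))
      intens <- exp(z + shifts[batch, , drop = FALSE])
      dimnames(intens) <- list(clin$sample_id, met_ids)
      tier <- flip(base_tier)
      q <- tier_q(tier)
      mat <- inject_missingness(abundance_matrix(intens, batch), q)
      list(abundance = mat, clinical = clin, tier = setNames(tier, met_ids),
           censor_quantiles = setNames(q, met_ids),
           latent = if (config$keep_latent) z)
    }

    train <- gen_cohort(config$n_train, "T", FALSE)
    valid <- gen_cohort(config$n_valid, "V", config$cohort_shift)

    sig_var <- vapply(betas, function(b) sum(b^2), numeric(1))
    for (oc in config$outcomes) {
      scale <- if (oc == "density") 24 / 0.9 else 1
      tot <- sig_var[[oc]] + scale^2 *
        (covariate_variance(config$covariate_effects) + config$noise_sd^2)
      truth[[oc]] <- list(
        true_support = met_ids[betas[[oc]] != 0],
        true_coefficients = setNames(betas[[oc]][betas[[oc]] != 0],
                                     met_ids[betas[[oc]] != 0]),
        true_covariate_effects = lapply(config$covariate_effects, `*`, scale),
        generative_r2 = if (tot > 0) sig_var[[oc]] / tot else 0
      )
    }
    truth$censor_quantiles <- list(train = train$censor_quantiles,
                                   valid = valid$censor_quantiles)
    truth$tiers <- list(train = train$tier, valid = valid$tier)
    if (config$keep_latent)
      truth$latent <- list(train = train$latent, valid = valid$latent)

    list(train = train[c("abundance", "clinical")],
         valid = valid[c("abundance", "clinical")],
         truth = truth)
  })
}

#' Left-censor an abundance matrix at per-metabolite quantiles
#'
#' Emulates abundance-dependent missingness: for each metabolite, the lowest
#' `round(q * n_observed)` intensities are set to `NA`, so the observed
#' missing fraction tracks the requested quantile. `q = 0` leaves the
#' metabolite complete; `q = 1` censors it entirely. Censoring is
#' deterministic given the matrix; `seed` only randomizes the order in which
#' tied intensities are censored.
#'
#' @param mat an [abundance_matrix()].
#' @param censor_quantiles numeric vector in `[0, 1]`, recycled across
#'   metabolites.
#' @param seed optional integer for tie-breaking among equal intensities.
#' @return An [abundance_matrix()] with additional `NA`s.
#' @export
inject_missingness <- function(mat, censor_quantiles, seed = NULL) {
  stopifnot(inherits(mat, "abundance_matrix"))
  q <- rep_len(censor_quantiles, ncol(mat$values))
  if (any(q < 0 | q > 1)) stop("censor quantiles must lie in [0, 1]")
  v <- mat$values
  censor_one <- function(x, qj) {
    obs <- which(!is.na(x))
    m <- round(qj * length(obs))
    if (m > 0) {
      o <- order(x[obs], if (is.null(seed)) seq_along(obs) else runif(length(obs)))
      x[obs[o[seq_len(m)]]] <- NA_real_
    }
    x
  }
  if (!is.null(seed)) {
    v <- withr::with_seed(seed, {
      for (j in seq_len(ncol(v))) v[, j] <- censor_one(v[, j], q[j])
      v
    })
  } else {
    for (j in seq_len(ncol(v))) v[, j] <- censor_one(v[, j], q[j])
  }
  abundance_matrix(v, mat$batch, mat$metabolite_meta)
}

#' Write a synthetic cohort pair to plain-text files
#'
#' Emits, per cohort, the abundance TSV (see [write_abundance_tsv()]) and the
#' clinical CSV, plus the ground-truth record as JSON.
#'
#' @param pair result of [generate_cohort_pair()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_cohort_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    train_abundance = file.path(dir, "train_abundance.tsv"),
    train_clinical = file.path(dir, "train_clinical.csv"),
    valid_abundance = file.path(dir, "valid_abundance.tsv"),
    valid_clinical = file.path(dir, "valid_clinical.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_abundance_tsv(pair$train$abundance, files["train_abundance"])
  write.csv(pair$train$clinical, files["train_clinical"], row.names = FALSE)
  write_abundance_tsv(pair$valid$abundance, files["valid_abundance"])
  write.csv(pair$valid$clinical, files["valid_clinical"], row.names = FALSE)
  jsonlite::write_json(pair$truth, files["truth"], auto_unbox = TRUE, digits = I(17))
  invisible(files)
}
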