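#' Run the full severity-score pipeline from a single configuration
#'
#' Orchestrates an end-to-end run: obtain the two cohorts (either generated
#' by [generate_cohort_pair()] from an inline `synth` block, or loaded from
#' abundance/clinical files), batch-normalize, subject-QC, tier and
#' harmonize the metabolites, build train/validation designs with one
#' recipe, fit the cross-validated adaptive LASSO (optionally with
#' extreme-quintile observation weights), build and apply the severity
#' score, evaluate the three regression models in both cohorts, summarize
#' predicted-vs-observed calibration, and (optionally) run pathway
#' over-representation on the selected metabolites. Every stage logs its
#' counts; all randomness flows from `config$seed`.
#'
#' @param config a named list or path to a YAML file. Recognized fields:
#'   `synth` (list of [synth_config()] arguments) or `files` (named paths
#'   `train_abundance`, `train_clinical`, `valid_abundance`,
#'   `valid_clinical`); `outcome` (column name(s), default `"fev1"`);
#'   `covariates` (default the clinical set: sex, age, height, race, bmi,
#'   smoking status, pack-years, site); `k` (kNN, default 10); `folds`
#'   (default 10); `seed`; `weight_factor` (extreme-quintile factor, `NULL`
#'   for unweighted); `swap` (also run with cohorts exchanged);
#'   `pathway_gmt` / `pathway_edges` (over-representation inputs);
#'   `out_dir` (write artifacts + manifest there).
#' @param out_dir overrides `config$out_dir`.
#' @return A list with one element per outcome, each containing `forward`
#'   (and `reverse` when swapped) direction results (`fit`, `metss`,
#'   `scores`, `evals`, `pred_vs_obs`, `plan`, `ora`), plus
#'   `cohort_comparison` and, when artifacts are written, the `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out_dir
  outcome <- config$outcome %||% "fev1"
  covars <- config$covariates %||%
    c("sex", "age", "height", "race", "bmi", "smoking_status", "pack_years", "site")
  k <- config$k %||% 10
  folds <- config$folds %||% 10
  seed <- config$seed %||% 1

  if (!is.null(config$synth)) {
    scfg <- do.call(synth_config, c(config$synth,
                                    if (is.null(config$synth$seed)) list(seed = seed)))
    message("synth: generating cohort pair (seed ", scfg$seed, ")")
    pair <- generate_cohort_pair(scfg)
    train <- pair$train; valid <- pair$valid; truth <- pair$truth
  } else if (!is.null(config$files)) {
    f <- config$files
    train <- list(abundance = read_abundance_tsv(f$train_abundance),
                  clinical = read.csv(f$train_clinical, stringsAsFactors = FALSE))
    valid <- list(abundance = read_abundance_tsv(f$valid_abundance),
                  clinical = read.csv(f$valid_clinical, stringsAsFactors = FALSE))
    truth <- NULL
  } else stop("config needs either a 'synth' block or 'files' paths")

  pathways <- NULL
  if (!is.null(config$pathway_gmt))
    pathways <- read_pathways(config$pathway_gmt, config$pathway_edges)

  cmp_vars <- intersect(c(covars, outcome), intersect(names(train$clinical),
                                                      names(valid$clinical)))
  comparison <- cohort_compare(train$clinical, valid$clinical, cmp_vars)

  results <- list(cohort_comparison = comparison, truth = truth)
  for (oc in outcome) {
    res <- list(forward = run_direction(train, valid, oc, covars, k, folds,
                                        seed, config$weight_factor, pathways))
    if (isTRUE(config$swap))
      res$reverse <- run_direction(valid, train, oc, covars, k, folds,
                                   seed, config$weight_factor, pathways)
    results[[oc]] <- res
  }

  if (!is.null(out_dir))
    results$manifest <- write_run_artifacts(results, outcome, config, out_dir)
  invisible(results)
}

#' Prepare aligned train/validation designs from a cohort pair
#'
#' The shared preprocessing front end of the pipeline: within-batch median
#' normalization, subject QC, missingness tiering of each cohort,
#' cross-cohort harmonization, and design construction for both cohorts from
#' the single training recipe.
#'
#' @param train,valid lists with `abundance` (an [abundance_matrix()]) and
#'   `clinical` (a data.frame keyed by `sample_id`), as produced by
#'   [generate_cohort_pair()] or loaded from files.
#' @param outcome outcome column name in the clinical tables.
#' @param k kNN imputation neighbour count.
#' @return A list with `train`/`valid` sublists (`design`, `clinical`, `y`),
#'   the harmonization `plan`, the training `recipe`, and per-cohort QC
#'   results.
#' @export
build_paired_design <- function(train, valid, outcome, k = 10) {
  prep <- function(cohort, label) {
    norm <- batch_median_normalize(cohort$abundance)
    qc <- subject_qc_filter(norm)
    message(label, ": subject QC kept ", length(qc$kept), "/",
            nrow(cohort$abundance$values), " samples")
    list(abundance = subset_samples(cohort$abundance, qc$kept),
         norm = subset_samples(norm, qc$kept),
         clinical = cohort$clinical[match(qc$kept, cohort$clinical$sample_id), ],
         qc = qc)
  }
  tr <- prep(train, "train")
  va <- prep(valid, "valid")

  # missingness patterns are unchanged by normalization, so the QC-subset
  # normalized matrices serve for tiering
  plan <- harmonize(categorize_missingness(tr$norm),
                    categorize_missingness(va$norm))
  cnt <- attr(plan, "counts")
  message(sprintf(
    "harmonize: %d shared -> %d continuous + %d indicator (%d dropped, %d discordant)",
    cnt["common"], cnt["continuous"], cnt["indicator"],
    cnt["dropped_either"], cnt["discordant"]))

  des_tr <- make_design(tr$abundance, plan, k = k)
  des_va <- make_design(va$abundance, recipe = des_tr$recipe)
  list(
    train = list(design = des_tr$design, clinical = tr$clinical,
                 y = tr$clinical[[outcome]]),
    valid = list(design = des_va$design, clinical = va$clinical,
                 y = va$clinical[[outcome]]),
    plan = plan, recipe = des_tr$recipe,
    qc = list(train_removed = tr$qc$removed, valid_removed = va$qc$removed)
  )
}

# One train -> validation direction of the pipeline.
run_direction <- function(train, valid, outcome, covars, k, folds, seed,
                          weight_factor = NULL, pathways = NULL) {
  paired <- build_paired_design(train, valid, outcome, k = k)
  plan <- paired$plan
  tr <- paired$train
  va <- paired$valid
  y_tr <- tr$y
  w <- if (!is.null(weight_factor) && weight_factor != 1)
    extreme_quintile_weights(y_tr, weight_factor) else NULL

  fit <- cv_adalasso(tr$design, y_tr, folds = folds, seed = seed,
                     obs_weights = w)
  message("fit: ", length(fit$selected), " features selected at lambda = ",
          signif(fit$lambda_min, 4))
  score <- build_metss(fit)
  scores <- list(train = apply_metss(score, tr$design),
                 valid = apply_metss(score, va$design))

  evals <- list(
    train = eval_models(y_tr, scores$train, tr$clinical[covars]),
    valid = eval_models(va$y, scores$valid, va$clinical[covars])
  )
  pvo <- list(train = predicted_vs_observed(y_tr, scores$train),
              valid = predicted_vs_observed(va$y, scores$valid))

  ora <- NULL
  if (!is.null(pathways)) {
    selected_mets <- sub("^(log|det)_", "", score$features)
    universe <- intersect(plan$metabolite,
                          unique(unlist(lapply(pathways, `[[`, "members"))))
    ora <- ora_analysis(intersect(selected_mets, universe), pathways, universe)
    message("pathways: ", sum(ora$fdr < 0.10), " of ", nrow(ora),
            " over-represented at FDR < 0.10")
  }

  list(fit = fit, metss = score, scores = scores, evals = evals,
       pred_vs_obs = pvo, plan = plan, recipe = paired$recipe, ora = ora,
       qc = paired$qc)
}

#' Run the pipeline in both cohort directions
#'
#' Sensitivity analysis exchanging the training and validation roles; the
#' reverse direction is identical to a forward run with the cohort inputs
#' swapped.
#'
#' @inheritParams run_pipeline
#' @return As [run_pipeline()] with both `forward` and `reverse` filled in.
#' @export
swap_cohorts <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config$swap <- TRUE
  run_pipeline(config, out_dir)
}

# Write per-outcome artifacts plus a hash manifest; returns the manifest.
write_run_artifacts <- function(results, outcomes, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(p) { paths[[length(paths) + 1L]] <<- p; p }

  write.table(results$cohort_comparison,
              add(file.path(out_dir, "cohort_comparison.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (oc in outcomes) {
    for (dir_name in intersect(c("forward", "reverse"), names(results[[oc]]))) {
      d <- results[[oc]][[dir_name]]
      stem <- file.path(out_dir, paste(oc, dir_name, sep = "_"))
      write_fit_json(d$fit, add(paste0(stem, "_fit.json")))
      write_cv_tsv(d$fit, add(paste0(stem, "_cv.tsv")))
      write_metss_json(d$metss, add(paste0(stem, "_metss.json")))
      write_model_eval_tsv(d$evals, add(paste0(stem, "_eval.tsv")))
      pv <- do.call(rbind, lapply(names(d$pred_vs_obs), function(ch)
        data.frame(cohort = ch, slope = d$pred_vs_obs[[ch]]$slope,
                   intercept = d$pred_vs_obs[[ch]]$intercept)))
      write.table(pv, add(paste0(stem, "_pred_vs_obs.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(d$ora)) write_ora_tsv(d$ora, add(paste0(stem, "_ora.tsv")))
    }
  }
  manifest <- list(
    config = config,
    artifacts = lapply(setNames(nm = unlist(paths)), function(p)
      list(md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  manifest
}
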