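# metssr — metabolomic severity scores via adaptive LASSO

`metssr` builds **metabolomic severity scores** (metSS): sparse linear
predictors of a continuous clinical outcome — airflow obstruction
(FEV₁, liters) or CT lung density (g/L) are the motivating cases — from
untargeted plasma metabolomics profiled in two independent cohorts of
ever-smokers. It is aimed at biostatisticians and computational
biologists who have a training cohort, a validation cohort, and a
sample-by-metabolite intensity table with the usual pathologies: batch
effects, abundance-dependent missingness, and far more metabolites than
subjects.

## The method

The score is `ŷᵢ = β₀ + Σⱼ βⱼ xᵢⱼ` over harmonized metabolite features,
with support and weights chosen by a two-stage **adaptive LASSO**:

1. Ridge regression (penalty chosen by 10-fold CV, solved by SVD) supplies
   per-feature penalty factors `vⱼ = 1/|β̂ʳⁱᵈᵍᵉⱼ|` (capped at 10⁶).
2. Coordinate descent minimizes
   `(1/2n) Σᵢ wᵢ (yᵢ − β₀ − xᵢᵀβ)² + λ Σⱼ vⱼ |βⱼ|`
   down a 100-point λ path; λ is picked at the minimum mean out-of-fold
   MSE over 10 folds. By default the adaptive weights are re-estimated
   inside each training fold (see the methods vignette for why).

Around the solver sits the full pipeline: within-batch median
normalization; subject QC by median metabolite z-score (> 3 SD removed);
missingness tiering (< 20% → kNN-imputed continuous feature, k = 10;
20–80% → present/absent indicator; > 80% → dropped); cross-cohort
harmonization keeping only tier-concordant metabolites; natural-log
transform; evaluation by Wherry adjusted R² `1 − (1−R²)(n−1)/(n−p−1)`,
MSE, and partial F-tests for covariates-only / score-only /
score-plus-covariates models; cohort-swap and extreme-quintile-weighting
sensitivity analyses; and hypergeometric pathway over-representation with
BH FDR and centrality-based pathway impact. A synthetic two-cohort
generator with known ground truth makes every stage testable without
controlled-access data.

## A worked example

```r
library(metssr)

cfg <- list(
  synth = list(n_train = 200, n_valid = 200, p_metabolites = 120,
               n_blocks = 12, n_true_effects = 8, effect_sd = 0.35, seed = 7),
  folds = 5, seed = 7)
res <- run_pipeline(cfg)
#> synth: generating cohort pair (seed 7)
#> train: subject QC kept 200/200 samples
#> valid: subject QC kept 198/200 samples
#> harmonize: 120 shared -> 72 continuous + 9 indicator (30 dropped, 9 discordant)
#> fit: 17 features selected at lambda = 0.006913

fw <- res$fev1$forward
print(fw$fit)
#> adalasso_fit: 17 features selected of 81 at lambda = 0.006913 (5-fold CV, n = 200)
print(fw$evals$valid)
#>                  model   n  p adj_r2_pct       mse
#>        covariates_only 198 11       9.0% 1.3152166
#>             metss_only 198  1      31.1% 1.0492083
#>  metss_plus_covariates 198 12      40.8% 0.8507639
#> combined vs covariates-only: F = 101.00, p = 3.09e-19
```

Reading the output: 120 generated metabolites harmonize down to 81 model
features (72 continuous, 9 present/absent); the CV-chosen model keeps 17
of them, including all 8 with true effects. In the held-out cohort the
score alone explains 31.1% of outcome variance versus 9.0% for clinical
covariates, and adding the score to the covariates raises adjusted R²
from 9.0% to 40.8% (partial F = 101, p ≈ 3e-19) — the pattern a useful
severity score should show. `res$fev1$forward$metss` holds the portable
score (features, weights, intercept; `write_metss_json()` serializes it),
and `apply_metss()` scores any design built with the training recipe.

Sensitivity analyses: `swap_cohorts(cfg)` exchanges the cohort roles;
`cfg$weight_factor <- 5` reruns the fit with the outcome's extreme
quintiles up-weighted by 5. Supplying `cfg$pathway_gmt` (a GMT file,
optionally with per-pathway edge-list sidecars) adds hypergeometric
over-representation of the selected metabolites with BH FDR and pathway
impact.

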