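---
title: "Metabolomic severity scores: models, choices, and what the synthetic benchmarks show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolomic severity scores: models, choices, and what the synthetic benchmarks show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`metssr` builds a *metabolomic severity score* (metSS) for a continuous
clinical outcome — the motivating use case is airflow obstruction (FEV~1~,
liters) and CT lung density (g/L) in ever-smokers — from untargeted plasma
metabolomics profiled in two independent cohorts. The score is a sparse
linear predictor over harmonized metabolite features,

$$\widehat{y}_i \;=\; \beta_0 + \sum_{j \in S} \beta_j\, x_{ij},$$

whose support $S$ and weights $\beta_j$ are chosen by a two-stage
**adaptive LASSO**: a ridge regression supplies per-feature penalty factors
$v_j = 1/|\hat\beta^{\mathrm{ridge}}_j|$, and an L1-penalized fit with
those factors,

$$\min_{\beta_0,\beta}\; \frac{1}{2n}\sum_i w_i\bigl(y_i - \beta_0 -
x_i^\top\beta\bigr)^2 \;+\; \lambda \sum_j v_j\,|\beta_j|,$$

does selection and estimation simultaneously. Features with strong initial
signal are shrunk less; features with near-zero ridge coefficients are
effectively excluded (penalty factors are capped at $10^6$). The penalty
$\lambda$ is chosen by 10-fold cross-validation at the minimum mean
out-of-fold MSE (the "lambda-min" rule, not the one-SE rule). Clinical
covariates are deliberately **not** part of the score: a metabolite-only
score is a standalone blood measure, and covariates enter only at
evaluation time.

Evaluation fits three ordinary least-squares models per cohort —
covariates only, score only, score plus covariates — and reports the
Wherry-shrunken adjusted $R^2$,

$$R^2_{\mathrm{adj}} = 1 - (1 - R^2)\,\frac{n-1}{n-p-1},$$

MSE ($\mathrm{RSS}/n$), and a partial F-test of the combined model against
the covariates-only model. The `variant = "n-p"` denominator found in older
literature is available by flag; the default matches mainstream regression
output.

## Preprocessing contract

Raw intensities pass through a fixed sequence, recorded in a *recipe* so a
validation cohort is prepared identically to the training cohort:

1. **Within-batch median normalization** — each metabolite is divided by
   its within-batch median of observed values, so every (batch, metabolite)
   stratum has median 1. A stratum with no observed values is left as-is
   with a warning; the tiers below deal with it.
2. **Subject QC** — metabolites are z-scored across samples (population
   SD); each subject is summarized by its median z-score; subjects more
   than 3 SD from the cohort mean of those medians are removed.
3. **Missingness tiers** — per metabolite, the observed missing fraction
   maps to `IMPUTE` (< 20%), `INDICATOR` (20–80% inclusive: the boundary
   fractions 0.20 and 0.80 both dichotomize), or `DROP` (> 80%).
4. **Harmonization** — restricted to metabolites present in both cohorts,
   only tier-concordant metabolites survive: both-`IMPUTE` as continuous,
   both-`INDICATOR` as a present/absent 0/1 feature; discordant or
   either-`DROP` metabolites are excluded. This is why a tool applied to
   two real cohorts retains notably fewer features than either cohort
   alone.
5. **Log transform and kNN imputation** — continuous features are
   natural-log transformed (a normalized value of 1 maps to 0; nonpositive
   normalized values are set missing before imputation, with a message) and
   missing cells are filled by the unweighted mean of the k = 10 nearest
   samples. Distance is Euclidean over the features observed in both
   samples, scaled by the shared-feature count; only donors with the target
   feature observed are eligible.

Two orderings were genuinely open. We impute **after** the log transform,
because distances on raw intensities would be dominated by high-abundance
metabolites; and kNN distances use all pairwise-complete features rather
than only fully observed ones, so samples with disjoint missingness remain
comparable. Both choices are pinned by brute-force oracle tests.

Tobacco-related metabolites receive no special treatment: their
present/absent indicators arise from the same 20–80% rule as any other
metabolite.

## Numerical choices in the solver

The L1 fit is cyclic coordinate descent with soft-thresholding, warm starts
down a 100-point log-spaced grid from $\lambda_{\max}$ (the smallest
penalty at which every penalized coefficient is zero) to
$\lambda_{\max}\cdot 10^{-4}$, and active-set iteration between full
passes. Columns are standardized internally to weighted mean 0 and SD 1
(penalties are scale-dependent; indicator columns are standardized like
continuous ones, switchable), and coefficients are returned on the input
scale. Observation weights are normalized to sum to $n$, which makes the
solution invariant to their overall scale. Convergence demands both a full
sweep whose largest standardized-coefficient change is below $10^{-8}$
*and* a full Karush–Kuhn–Tucker check (residual below $10^{-8}$); hitting
the iteration cap raises an error carrying the violation, never a silent
return.

Three path-level controls keep the procedure fast at study scale
(n ≈ 650, ~600 features) without touching the region where model selection
happens; each mirrors standard practice in the penalized-regression
ecosystem:

* **Saturation stop** — the path ends once training $R^2$ exceeds 0.999 or
  improves by less than $10^{-5}\cdot R^2$ per grid point.
* **Size bound** — inside cross-validation the path also ends once the
  active set exceeds $\lfloor n/2\rfloor$ features: models that large are
  saturated interpolants the out-of-fold MSE minimum cannot select (the
  chosen model is typically 5–20 times smaller).
* **Fold tolerance** — fold fits, whose only product is out-of-fold MSE,
  converge at $10^{-5}$ (KKT $10^{-4}$); the final returned fit always uses
  the strict criteria. The cross-validation curve is restricted to the grid
  points every fold reached, and the reported grid is truncated to match,
  so the curve length always equals the stored grid length.

The ridge initialization solves its normal equations through one economy
SVD of the square-root-weighted design (stable for $p > n$ when the
penalty is positive), and the ridge penalty is chosen by 10-fold
cross-validation on the *same* fold partition as the LASSO, evaluating the
whole grid from a single SVD per fold. How the ridge penalty ought to be
chosen is not standardized in adaptive-LASSO practice; CV at minimum MSE
is our documented, configurable default.

### Fold-honest adaptive weights

One design question deserves its own section. Common glmnet-style practice
computes the adaptive penalty factors once, from the full training data,
and then cross-validates $\lambda$ re-using those factors in every fold.
But full-data ridge coefficients encode each held-out fold's noise, so
out-of-fold MSE is biased downward at small penalties and the selected set
inflates. The effect is not subtle: in our block-correlated benchmark
(n = 500, p = 800, 20 true effects), weights-once adaptive LASSO averaged
~114 false positives against the plain LASSO's ~66, erasing the adaptive
estimator's selection advantage entirely; with weights re-estimated inside
each training fold it averaged ~33. `cv_adalasso()` therefore re-estimates
the ridge weights per training fold by default (`fold_weights = TRUE`,
one extra ridge solve per fold at the globally chosen ridge penalty); the
weights-once convention remains available as `fold_weights = FALSE` for
strict emulation of the glmnet workflow.

A consequence worth knowing: the characteristic *shrinkage bias* of
overfit scores — held-out observed-on-predicted regression slope below 1,
with the highest outcomes under-predicted and the lowest over-predicted —
is largely a product of the leaky convention. Under weights-once our
validation slopes fall below 1 in 9 of 10 benchmark seeds; under the
fold-honest default the score is nearly calibrated (slopes 0.91–1.26, mean
≈ 1.02, below 1 in only 5 of 10). A user who wants to reproduce the
slope-below-1 pattern should run with `fold_weights = FALSE`.

## Sensitivity analyses

* **Cohort swap** (`swap_cohorts()` or `swap: true`) — the whole pipeline
  reruns with training and validation roles exchanged; the reverse
  direction is bit-identical to a forward run on pre-swapped inputs.
* **Extreme-quintile weighting** (`extreme_quintile_weights()`,
  `weight_factor: 5`) — samples in the bottom or top outcome quintile
  (rank-based membership, exactly $\lceil n/5\rceil$ per tail under ties)
  receive observation weight 5 in both the ridge initialization and the
  LASSO stages, penalizing mispredictions of extreme subjects.

## Pathway over-representation

Selected metabolites (indicator or continuous; the `log_`/`det_` prefix is
stripped) are tested against user-supplied GMT pathway sets by the
hypergeometric upper tail $P(X \ge k)$ — the observed overlap counts, as
in standard over-representation analysis — with Benjamini–Hochberg FDR
across pathways. The universe defaults to the harmonized metabolites
mappable to at least one supplied pathway, matching over-representation
convention. Where a pathway ships a directed reaction graph (edge-list
sidecar), *pathway impact* is the matched metabolites' summed centrality —
exact betweenness or out-degree, selectable — normalized by the total
centrality of the pathway, in [0, 1]. No pathway database is bundled;
content is the user's. Neither impact mode claims to replicate any web
server's weighting bit-for-bit.

## The synthetic cohort generator

Because the motivating cohorts are controlled-access, every claim the
package makes is exercised on synthetic cohorts with known ground truth.
The generator's defaults *are* the study conditions: a training cohort of
650 and a validation cohort of 1120 subjects; 762 metabolites in blocks of
~20 with within-block equicorrelation 0.5; 25 true effects of equal
magnitude and random sign, one per block; clinical covariates (sex, age,
height — the dominant covariate effect — BMI, smoking, pack-years, site)
with realistic marginals and cohort shifts (the validation cohort is ~4
years older, less diverse, with fewer current smokers and different site
labels); multiplicative per-batch intensity effects (log-scale SD 0.3,
4 batches per cohort); and abundance-dependent left-censoring that lands
~72% of metabolites in the fully quantified tier, ~12% in the
present/absent tier, and the rest in the excluded tier, with a 7% per-cohort
tier-flip probability creating cross-cohort discordance. The residual SD is
derived in closed form so that metabolites contribute 60% of outcome
variance; the implied covariate variance uses exact censored-normal
moments for pack-years.

Two deliberate choices: missingness is *left-censored* (low abundance →
missing), the dominant mechanism in untargeted metabolomics and the reason
present/absent indicators carry signal at all; and true-effect metabolites
are always placed in the fully quantified tier of both cohorts, because an
effect carried by a censored-away metabolite is unrecoverable by any
method and support-recovery benchmarks would conflate solver quality with
censoring luck.

What the generator does **not** emulate: mass-spectral artifacts,
annotation ambiguity, nonlinear metabolite–outcome relationships,
cross-cohort heterogeneity in the true coefficients (the same biological
truth underlies both cohorts), and non-fasting/fasting differences between
real cohorts. Passing benchmarks therefore demonstrate that the pipeline's
machinery is correct and well-calibrated under its stated assumptions —
not that a real two-cohort transfer will match the benchmark's validation
$R^2$, which in real data is further eroded by exactly the heterogeneity
the generator omits.

## Benchmark problem sizes

The heavy validation (10 seeds at the full study scale, adaptive and plain
LASSO under the identical protocol) runs in a few minutes on one core;
unit and oracle tests are seconds. Small-instance oracles are exhaustive:
sign-pattern enumeration and dense grid search for the solver (p ≤ 8),
brute-force neighbor enumeration for imputation (≤ 8×6), binomial-sum
tails for the hypergeometric test (N ≤ 25), and all-paths enumeration for
betweenness (≤ 7 nodes).

## Known limitations

* The adaptive LASSO inherits linearity; interactions or nonlinear dose
  effects are out of scope.
* Adjusted-$R^2$ point estimates carry no uncertainty intervals.
* The kNN distance treats all continuous features equally; informative
  missingness beyond the left-censoring mechanism is not modeled.
* With `fold_weights = FALSE` the cross-validated penalty is biased low;
  that mode exists for compatibility, not recommendation.
* GMT pathway content and compound-id mapping are entirely the user's
  responsibility; no translation service is consulted.
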