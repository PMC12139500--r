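---
title: "Flexible transfer models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible transfer models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the statistical model behind `flextransfer`, the
reasoning behind its tunable parameters and numerical choices, what the
synthetic cohort generator does and does not emulate, and the design
decisions that were genuinely open.

## 1. The model and the transfer representation

### Penalized logistic regression by IRLS

The statin prediction model is a logistic regression
\[
P(Y=1\mid X) = \frac{1}{1+e^{-(\beta_0 + \beta_1 X_1 + \cdots + \beta_q X_q)}}
\]
fitted by minimizing the average binomial negative log-likelihood plus a
ridge penalty,
\[
f(\beta) = \frac{1}{n}\sum_i -\ell_i(\beta)
  + \frac{\lambda}{2}\sum_j \phi_j \beta_j^2 ,
\]
by iteratively reweighted least squares (IRLS). Averaging over \(n\) makes
\(\lambda\) comparable across cohort sizes. The penalty factors \(\phi_j\)
are 1 for lipid species and 0 for the intercept and the adjustment
covariates (age, sex): shrinking confounder adjustments would re-introduce
the bias the adjustment exists to remove, and nothing in the prediction
problem asks for it. The factor is a regular argument, so the alternative
(penalizing everything) is one call away.

Ridge estimation is not scale-invariant, so predictors are standardized
internally (mean 0, sample SD 1; constant columns pass through with scale
1) and coefficients are reported back on the input scale. Lipid
concentrations enter all models on the natural-log scale —
`log_transform()` is a required, explicit step, and model-building
functions refuse cohorts that have not been transformed.

Each IRLS step solves
\[
\left(\tfrac{1}{n}X^\mathsf{T} W X + \lambda P\right)\beta^{new}
  = \tfrac{1}{n}X^\mathsf{T} W z,
\qquad
W_{ii} = p_i(1-p_i),\quad
z = X\beta + W^{-1}(y-p),
\]
with step-halving whenever the penalized objective fails to decrease, so
the training objective is non-increasing across iterations. The solver
iterates past the deviance plateau until the penalized gradient's infinity
norm is below `tol_grad` (default `1e-11`; quadratic convergence typically
lands near `1e-14` one step later). A fit is flagged `converged` when that
norm is below `1e-7`. The aggressive default matters: the transfer
representation below is exact *at the fixed point*, and a sloppy optimum
would show up directly as reconstruction error.

Probabilities inside IRLS are clipped to `[1e-10, 1-1e-10]` (predictions
to `[1e-12, 1-1e-12]`), IRLS is capped at 100 iterations, and
non-convergence is reported, never silent.

### Cross-validated penalty selection

`cross_validate_lambda()` runs 10-fold cross-validation, stratified by
outcome, over a descending log-spaced grid of 100 values from
\(\lambda_{max} = \max_j |x_j^\mathsf{T}(y-\bar y)|/(0.001\,n)\)
(computed over penalized, standardized predictors) down to
\(10^{-4}\lambda_{max}\). The selected `lambda_min` minimizes the mean
held-out binomial deviance; among exact ties the smallest \(\lambda\)
(least regularization) wins. Fold assignment is a deterministic function
of the `seed` argument, and the caller's RNG stream is never touched.
Within each training fold the path is fitted with warm starts down the
grid at a looser gradient tolerance (`1e-7`) — held-out deviance is flat
at that precision — while final models always use the strict tolerance.

### The transfer matrices

At a penalized IRLS fixed point,
\(X^\mathsf{T}W z = (X^\mathsf{T}WX + n\lambda P)\hat\beta\). Storing
\[
M = X^\mathsf{T}WX + n\lambda P, \qquad
\upsilon = X^\mathsf{T}W z
\]
(on the standardized design, intercept column included) therefore lets
anyone recover \(\hat\beta = M^{-1}\upsilon\) exactly, and — the point of
the whole construction — re-estimate coefficients for any predictor
subset \(J\) as \(\hat\beta_{reduced} = M_{J,J}^{-1}\upsilon_J\), with no
refitting and no individual-level data. Two choices here deserve
justification:

* **\(\upsilon\) uses the working response, not the fitted log odds.**
  The two coincide exactly at \(\lambda = 0\), where the score equation
  gives \(X^\mathsf{T}(y-p)=0\) (a unit test pins this equivalence). Under
  a ridge penalty the penalized score is \(n\lambda P\hat\beta \neq 0\),
  and only the working-response form preserves the full-set identity.
  Since the models this package fits are ridge models, exactness of the
  identity is taken as the governing contract.
* **\(M\) carries the penalty term \(n\lambda P\)**, so a re-weighted
  subset model inherits the same regularization it was trained with.

Transfer matrices live on the standardized scale; the bundle stores the
per-variable (mean, SD) so incoming data can be standardized identically,
and subset models are back-transformed for reporting. Subsetting after
back-transformation would entangle the scales of retained and dropped
variables. The intercept and the unpenalized covariates are
non-droppable (`always_keep`): the subsets of interest are lipid panels,
never the adjustment set.

Numerically, every \(M_{J,J}\) solve uses a Cholesky factorization —
explicit inversion is never performed. If the condition number exceeds
`1e12` the solve falls back to least squares, warns, and flags the
returned fit (`solve_fallback`). Bundles serialize to versioned JSON with
base64-encoded IEEE doubles (bit-exact round trip) and a byte-sum
checksum; truncated or tampered files fail loudly.

The re-weighting formula is a heuristic outside the full set: it is
accurate while the excluded variables change predicted probabilities
little, or proportionally across individuals. No formal error bound
exists, so the package's guarantees at reduced sets are empirical
(Section 4), not analytic.

## 2. The synthetic cohort generator

Access-controlled cohort data cannot ship with a package, so every
analysis stage is exercised on synthetic lipidomes with known ground
truth. `sim_config()` defaults describe a large adult population cohort
profiled on a targeted platform:

| parameter | default | meaning |
|---|---|---|
| `n_classes` × `species_per_class` | 30 × 25 = 750 | species panel size of a modern targeted platform |
| `within_class_corr` | 0.5 | equicorrelation of log concentrations within a lipid class; 0 between classes |
| `log_mean_range` | [−2, 3] | natural-log concentration means (arbitrary concentration units, consistent per lipid) |
| `log_sd` | 0.5 | per-species biological variation on the log scale |
| `statin_prevalence_target` | 0.084 | population statin prevalence; propensity intercept calibrated to hit it in expectation |
| `statin_effect_frac_negative` | 0.9 | fraction of species lowered by statin use — the strong predominance of decreases seen in intervention data |
| `statin_effect_scale` | 0.3 | half-normal scale of effect magnitudes on log concentration |
| `cvd_statin_beta` | −0.5 | direct (protective) statin effect on prevalent CVD; positive values build confounding-by-indication scenarios |

Log concentrations are drawn from a block-diagonal covariance —
equicorrelation within class, zero between — the simplest positive-definite
stand-in for lipid-class structure, generated exactly via a shared
per-class factor. Generation happens in log space and is exponentiated,
so concentrations are strictly positive by construction. Statin assignment
follows a logistic propensity on age and sex only (the model's adjustment
covariates); other covariates are drawn independently — the minimal
confounding structure that still exercises adjustment. Statin users' log
concentrations are shifted by the ground-truth effects; prevalent CVD is
then drawn from a logistic model on a subset of causal lipids
(post-statin) plus the direct statin term, which is what makes statin a
genuine confounder of lipid–CVD associations. Follow-up tables add the
statin shift under a caller-supplied post-randomization assignment plus
Gaussian log-scale noise, emulating a placebo-controlled trial with paired
samples.

What the generator does **not** emulate: mass-spectrometric batch drift,
missingness patterns, isotope/response correction, sample outliers,
pedigree structure, or platform-specific species panels. Passing tests
therefore demonstrate that the *statistical machinery* is correct under
the stated generative assumptions — not that any particular real-data
preprocessing pipeline is adequate.

## 3. Harmonization and association analyses

**Harmonization.** Cross-cohort correction factors are per-lipid ratios of
a consensus reference-material concentration to the cohort's median QC
measurement of that material (`qc_correction_factors()`); medians, not
means, throughout. Cohorts without QC measurements are aligned through
covariate-matched sub-cohorts: 1:1 nearest-neighbor matching without
replacement on standardized covariates, globally greedy (closest pair
first, ties by sample order — deterministic), then a ratio of sub-cohort
medians. The matching algorithm is deliberately the simplest defensible
choice and is isolated behind the function boundary. Factors apply on the
concentration scale, before the log transform. Consensus-panel
construction is out of scope — the panel is an input. QC replicates in the
generator use median-unbiased lognormal noise (log-mean 0), matching the
ratio-of-medians estimator.

**Statin-effect scan.** Per lipid, OLS of log follow-up concentration on
statin, log baseline concentration, their interaction, and covariates
(age, sex, BMI, hypertension medication, diabetes, smoking, systolic
blood pressure) plus clinical lipids — baseline values by default, or
12-month values to isolate effects on lipid metabolism from the bulk
lipoprotein change. Baseline concentrations enter on the log scale,
matching the outcome. "Blood pressure" is systolic throughout. Main
effects and interactions are corrected as separate families.

**CVD scan.** Per lipid, unpenalized ML logistic regression of prevalent
CVD on log concentration plus covariates, with and without statin as a
covariate; separation is detected and flagged per lipid. Multiple testing
uses Benjamini–Hochberg; Storey-type q-values are a plausible alternative
the package does not implement, and the documentation says so. The
three-tier classification (corrected p < 0.05 / nominal p < 0.05 / neither)
and its cross-tabulation quantify how many apparent associations statin
adjustment creates or removes.

## 4. The robustness-sweep protocol

`robustness_sweep()` compares three ways of applying a trained model to a
cohort missing lipids, across retained fractions 100% down to 10% in steps
of 10, with 10 random subsets per fraction (subset sizes round up,
\(\lceil f\,p\rceil\)). Within a (fraction, replicate) cell all methods
see the *same* lipid subset:

* **ftm_reweight** — `reweight()` on the transfer bundle;
* **truncated** — the full model with missing-lipid coefficients
  discarded (`truncated_predict()`), the field's default workaround;
* **refit** — a ridge model re-developed on the training data restricted
  to the subset, with its own full 10-fold cross-validated \(\lambda\).

Summaries are means and sample SDs (n−1) over replicates. Two protocol
details are the package's own choices. First, at the full lipid set the
"refit" is the original model itself: re-running cross-validation with a
different fold split would select a marginally different \(\lambda\) and
the three methods would differ by selection noise rather than by anything
the sweep measures; returning the original fit makes the 100% point an
exact identity for all three methods. Second, the per-subset refits use a
25-value \(\lambda\) grid spanning the same range as the default 100-value
grid: a sweep performs ~100 independent cross-validations, ridge
\(\lambda\) selection is insensitive to grid density, and in side-by-side
runs the selected penalties and AUCs were indistinguishable at a quarter
of the cost. Both are configurable (`sweep_config()`).

### Study conditions used by the tests and the acceptance script

The packaged robustness study generates one population of 6,000 samples ×
200 species (20 classes × 10, within-class correlation 0.5, statin
prevalence 30%, effect scale 0.12 — chosen so the full model validates
around AUC 0.99 rather than saturating at 1.0, leaving the low-overlap
regime informative) and splits it into a 4,000-sample training cohort and
a 2,000-sample external validation cohort that share the species panel —
the synthetic analogue of two cohorts profiled on one platform. On these
conditions the re-weighted model dominates truncation at every fraction
≤ 70% and tracks the refitted models within 0.02 AUC at every fraction,
the qualitative pattern the method is designed to produce. The
interval-coverage study uses 20 paired cohorts (n = 1,000, 50 species,
follow-up noise SD 0.2, 50:50 randomization); the confounding study uses
50 small cohorts in which statin strongly lowers a disease-null lipid
while being positively linked to prevalent CVD. These problem sizes are
the package's reference conditions; all are plain arguments.

## 5. Degenerate inputs and edge behavior

Single-class outcomes, non-finite design entries, rank-deficient OLS
designs (error names the collinear columns), unknown or re-ordered
predictor names at prediction time (exact name+order contract, no silent
reordering), zero concentrations (policy: replace with half the lipid's
smallest positive value, or error; negatives always error), duplicate
lipid columns and malformed numeric cells in input files (fatal, located)
are all explicit errors or flagged conditions, tested as such. Constant
predictor columns standardize with scale 1 and legitimately earn an exact
zero coefficient.

## 6. Known limitations

* The subset re-weighting formula has no analytic error bound; accuracy
  away from the full set is established empirically under the generator's
  assumptions.
* `reweight()` returns point coefficients only — no uncertainty intervals
  for re-weighted models.
* The generator's equicorrelated blocks are a caricature of real
  lipid-class covariance (no cross-class correlation, no platform batch
  structure), and statin propensity depends on age and sex only.
* Harmonization assumes a purely multiplicative, lipid-wise distortion
  between cohorts; additive or nonlinear platform differences are out of
  scope, as are within-cohort batch correction and imputation of
  unmeasured species.
* Only binomial models are supported; there is no transfer construction
  for other losses.
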