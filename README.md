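# flextransfer

Statin use reshapes the circulating lipidome: it lowers most lipid species
and is itself driven by cardiovascular risk, so any lipid–disease
association study that ignores it risks confounded effect estimates and
false-positive hits. Many cohorts, however, record medication use poorly or
not at all. `flextransfer` is an R package for lipidomics researchers who
want to (a) predict statin usage from a lipidomic profile with a ridge
(L2-penalized) logistic model, (b) carry that model to external cohorts
that measured only a subset of the training lipids — *without refitting and
without individual-level data* — and (c) quantify what statin adjustment
does to per-lipid association analyses.

## The flexible transfer model

A logistic model P(Y=1|X) = 1/(1+exp(−(β₀+Xβ))) fitted by iteratively
reweighted least squares (IRLS) satisfies, at convergence,

    β̂ = (XᵀWX)⁻¹ XᵀWz,   W_ii = p_i(1−p_i),

with z the IRLS working response (which equals the fitted log odds
logit(p) at an unpenalized optimum). Designating

    M = XᵀWX + nλP   and   υ = XᵀWz

(with P the diagonal of penalty factors, so M carries the ridge penalty),
the coefficients for **any subset J of the predictors** can be
re-estimated from the stored matrices alone:

    β̂_reduced = M_{J,J}⁻¹ υ_J .

Re-weighting redistributes the weight of missing, correlated lipids onto
the retained ones, where simple coefficient truncation just discards it.
At the full predictor set the reconstruction is an exact identity (to
1e−10), not an approximation. A transfer bundle — M, υ, variable names, λ,
penalty factors and standardization constants — is all a downstream cohort
needs; no individual-level data travel with it.

Around this core the package provides:

* `simulate_cohort()` / `simulate_followup()` / `simulate_qc_replicates()` —
  a synthetic lipidome generator with class-structured correlation,
  covariate-driven statin assignment and known ground-truth effects;
* `fit_ridge_logistic()`, `cross_validate_lambda()`, `fit_statin_model()` —
  the penalized IRLS engine with 10-fold cross-validated λ;
* `build_transfer_bundle()`, `reweight()`, `save_bundle()` / `load_bundle()` —
  the portable model representation;
* `qc_correction_factors()`, `matched_subcohort_factors()`,
  `apply_factors()`, `log_transform()` — cross-cohort concentration
  harmonization against a reference panel;
* `statin_effect_scan()`, `cvd_assoc_scan()`, `bh_adjust()`,
  `classify_and_crosstab()` — per-lipid association analyses with
  Benjamini–Hochberg correction and significance-class bookkeeping;
* `auc_score()`, `truncated_predict()`, `robustness_sweep()` — the
  evaluation protocol comparing re-weighted, truncated and refitted models
  across random predictor subsets, with `autoplot()` output.

All user-facing functions take a data frame first and return tibbles, so
analyses compose with the pipe; fitted objects support `tidy()` and
`glance()`.

## Worked example

Train a statin model on one cohort, then apply it to a target cohort that
only measured 20 of the 100 training lipids:

```r
library(flextransfer)

sim <- simulate_cohort(sim_config(
  n_samples = 3000, n_classes = 10, species_per_class = 10,
  statin_prevalence_target = 0.3, statin_effect_scale = 0.15, seed = 42))
lipids <- lipid_names(sim$cohort)
train  <- log_transform(as_lipid_cohort(sim$cohort[1:2000, ],    lipids))
target <- log_transform(as_lipid_cohort(sim$cohort[2001:3000, ], lipids))

model <- fit_statin_model(train, seed = 7)
model$fit
#> <ridge_fit>  102 predictors, lambda = 0.01734
#>   deviance = 499.7232, 7 IRLS iterations, converged: TRUE
model$bundle
#> <transfer_bundle v1.0>  103 variables (3 non-droppable), lambda = 0.01734, n_train = 2000

# the target cohort only has these 20 lipid species
overlap <- lipids[1:20]
reduced <- reweight(model$bundle, c(overlap, "age", "sex"))

x_target <- as.matrix(target[c(overlap, "age", "sex")])
auc_score(predict_proba(reduced, x_target), target$statin)
#> AUC, re-weighted to the 20-lipid overlap: 0.911
auc_score(truncated_predict(model$fit, c(overlap, "age", "sex"), x_target),
          target$statin)
#> AUC, coefficients simply truncated:       0.906
```

The re-weighted model recovers the coefficients a ridge model *refitted on
those 20 lipids* would have found — here it beats naive truncation, and
the gap widens as fewer lipids overlap (see the robustness sweep in the
vignette). `lambda = 0.01734` is the 10-fold cross-validated penalty;
"3 non-droppable" are the intercept and the unpenalized age/sex
adjustment covariates, which every subset retains.

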