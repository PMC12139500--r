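#' Area under the ROC curve (midrank Mann-Whitney)
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counted one half — computed from midranks,
#' equivalent to the Mann-Whitney U statistic and invariant under strictly
#' monotone transformations of the scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels) ||
      !all(labels %in% c(0, 1))) {
    abort("`scores` and `labels` must be aligned, complete, and labels 0/1.")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present to compute an AUC.")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Truncated prediction: drop coefficients of unmeasured predictors
#'
#' The naive way to apply a fitted model to data missing some predictors:
#' coefficients without a corresponding measurement are discarded
#' (equivalently set to zero) and the linear predictor is computed from the
#' remaining standardized variables with the original intercept. This is
#' the baseline the re-weighted transfer model is compared against.
#'
#' @param fit A `ridge_fit`.
#' @param variables Retained predictor names (subset of the fit's
#'   predictors).
#' @param newdata Matrix or data frame whose columns are exactly
#'   `variables`, in the fit's variable order.
#' @return Vector of probabilities.
#' @export
truncated_predict <- function(fit, variables, newdata) {
  stopifnot(inherits(fit, "ridge_fit"))
  variables <- as.character(variables)
  unknown <- setdiff(variables, fit$design$predictor_names)
  if (length(unknown) > 0) {
    abort(paste0("Variables not in the fit: ", paste(head(unknown, 5), collapse = ", ")))
  }
  keep <- fit$design$predictor_names[fit$design$predictor_names %in% variables]
  x <- as_design_matrix(newdata)
  if (!identical(colnames(x), keep)) {
    abort("Columns of `newdata` must be exactly the retained variables, in the fit's order.")
  }
  xs <- sweep(sweep(x, 2, fit$scaling$center[keep]), 2, fit$scaling$scale[keep], "/")
  eta <- fit$beta_std[["(Intercept)"]] + drop(xs %*% fit$beta_std[keep])
  pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
}

#' Robustness-sweep configuration
#'
#' @param fractions Fractions of lipid species retained, in (0, 1],
#'   descending (default 1.0 down to 0.1 in steps of 0.1).
#' @param n_reps Random lipid subsets drawn per fraction (default 10).
#' @param methods Any of `"ftm_reweight"` (re-weighted transfer model),
#'   `"truncated"` (coefficients of missing lipids discarded), `"refit"`
#'   (ridge model re-developed on the subset with fresh cross-validation).
#' @param seed Integer seed; fully determines the drawn subsets.
#' @param refit_n_lambda Grid length for the refits' cross-validated
#'   lambda selection (the full model's default grid is denser; ridge
#'   lambda selection is insensitive to grid density, and the sweep runs
#'   one full 10-fold CV per subset).
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(fractions = seq(1, 0.1, by = -0.1), n_reps = 10L,
                         methods = c("ftm_reweight", "truncated", "refit"),
                         seed = 1L, refit_n_lambda = 25L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (any(fractions <= 0 | fractions > 1)) abort("`fractions` must lie in (0, 1].")
  fractions <- sort(unique(fractions), decreasing = TRUE)
  if (n_reps < 1L) abort("`n_reps` must be at least 1.")
  structure(list(fractions = fractions, n_reps = as.integer(n_reps),
                 methods = methods, seed = as.integer(seed),
                 refit_n_lambda = as.integer(refit_n_lambda)),
            class = "sweep_config")
}

#' Robustness sweep: re-weighted vs truncated vs refitted models
#'
#' Implements the subset-robustness protocol: for each retained fraction f
#' (100% down to 10%) and each of `n_reps` resamples, draw a uniform random
#' subset of ceiling(f x p) lipid species — shared by all methods within
#' that (fraction, rep) — and score statin prediction on each validation
#' cohort by AUC. Methods: re-weighting the transfer bundle to the subset,
#' truncating the full model's coefficients, and re-developing a ridge
#' model (with 10-fold cross-validated lambda) on the training data
#' restricted to the subset. Adjustment covariates are always retained.
#'
#' @param bundle Transfer bundle of the full training model.
#' @param full_fit The full `ridge_fit` the bundle was built from.
#' @param train Log-transformed training `lipid_cohort` (used only by the
#'   `refit` method).
#' @param validation One log-transformed `lipid_cohort`, or a (optionally
#'   named) list of them.
#' @param config A [sweep_config()].
#' @param covariates Adjustment covariates in the model (default age, sex).
#' @return A `sweep_result` tibble: `fraction`, `rep`, `method`, `cohort`,
#'   `auc`, `n_lipids_kept`, `subset_seed`. Failed refits are recorded as
#'   `NA`, not fatal. Use [sweep_summary()] for per-(fraction, method)
#'   means and SDs and `autoplot()` to draw the sweep.
#' @export
robustness_sweep <- function(bundle, full_fit, train, validation, config,
                             covariates = c("age", "sex")) {
  stopifnot(inherits(bundle, "transfer_bundle"), inherits(full_fit, "ridge_fit"),
            inherits(config, "sweep_config"))
  if (inherits(validation, "lipid_cohort")) validation <- list(validation)
  if (is.null(names(validation))) {
    names(validation) <- paste0("cohort", seq_along(validation))
  }
  check_lipid_cohort(train, log_scale = TRUE)
  lapply(validation, check_lipid_cohort, log_scale = TRUE)

  lipids <- setdiff(full_fit$design$predictor_names, covariates)
  p <- length(lipids)
  for (vc in validation) {
    if (!all(lipids %in% lipid_names(vc)) || !all(covariates %in% names(vc))) {
      abort("Validation cohorts must contain the model's lipids and covariates.")
    }
  }

  train_design <- statin_design(train, lipids, covariates)
  val_designs <- lapply(validation, function(vc) {
    list(x = as.matrix(vc[c(lipids, covariates)]), y = vc$statin)
  })

  grid <- tidyr::expand_grid(fraction = config$fractions,
                             rep = seq_len(config$n_reps))
  grid$subset_seed <- config$seed + seq_len(nrow(grid))

  rows <- purrr::pmap(grid, function(fraction, rep, subset_seed) {
    keep_lipids <- with_seed(subset_seed, sample(lipids, ceiling(fraction * p)))
    keep_lipids <- lipids[sort(match(keep_lipids, lipids))]  # fit order
    vars <- c(keep_lipids, covariates)

    fits <- list()
    if ("ftm_reweight" %in% config$methods) {
      fits$ftm_reweight <- reweight(bundle, vars)
    }
    if ("refit" %in% config$methods) {
      # at the full lipid set the re-developed model IS the original model;
      # re-running CV with another fold split would only add selection noise
      fits$refit <- if (length(keep_lipids) == p) full_fit else tryCatch({
        pf <- c(rep(1, length(keep_lipids)), rep(0, length(covariates)))
        idx <- c(keep_lipids, covariates)
        fit_ridge_cv(train_design$x[, idx, drop = FALSE], train_design$y,
                     penalty_factors = pf, seed = subset_seed,
                     n_lambda = config$refit_n_lambda)$fit
      }, error = function(e) {
        warn(sprintf("Refit failed at fraction %.2f rep %d: %s",
                     fraction, rep, conditionMessage(e)))
        NULL
      })
    }

    purrr::imap(val_designs, function(vd, cohort_name) {
      xv <- vd$x[, vars, drop = FALSE]
      aucs <- purrr::map_dbl(config$methods, function(m) {
        if (m == "truncated") {
          return(auc_score(truncated_predict(full_fit, vars, xv), vd$y))
        }
        if (is.null(fits[[m]])) return(NA_real_)
        auc_score(predict_proba(fits[[m]], xv), vd$y)
      })
      tibble(fraction = fraction, rep = rep, method = config$methods,
             cohort = cohort_name, auc = aucs,
             n_lipids_kept = length(keep_lipids), subset_seed = subset_seed)
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- unique(c("sweep_result", class(out)))
  attr(out, "config") <- config
  out
}

#' Summarize a robustness sweep
#'
#' Mean and sample SD (n - 1 denominator) of the AUC over replicates, per
#' (cohort, fraction, method).
#'
#' @param result A [robustness_sweep()] result.
#' @return Tibble: `cohort`, `fraction`, `method`, `mean_auc`, `sd_auc`,
#'   `n_reps`.
#' @export
sweep_summary <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  result |>
    dplyr::group_by(.data$cohort, .data$fraction, .data$method) |>
    dplyr::summarise(mean_auc = mean(.data$auc, na.rm = TRUE),
                     sd_auc = sd(.data$auc, na.rm = TRUE),
                     n_reps = dplyr::n(), .groups = "drop")
}

# design matrix for the statin prediction recipe: log-lipids + covariates
statin_design <- function(cohort, lipids = NULL, covariates = c("age", "sex")) {
  check_lipid_cohort(cohort, log_scale = TRUE)
  lipids <- lipids %||% lipid_names(cohort)
  miss <- setdiff(covariates, names(cohort))
  if (length(miss) > 0) {
    abort(paste0("Missing covariates: ", paste(miss, collapse = ", ")))
  }
  list(x = as.matrix(cohort[c(lipids, covariates)]), y = cohort$statin,
       penalty_factors = c(rep(1, length(lipids)), rep(0, length(covariates))))
}

#' Fit the statin-usage prediction model on a cohort
#'
#' The standard recipe: log-transformed lipid species as penalized
#' predictors, age and sex as unpenalized adjustment covariates, statin
#' usage as the outcome; 10-fold cross-validation selects the ridge
#' penalty and a final model is fitted on all samples.
#'
#' @param cohort A log-transformed `lipid_cohort` with a `statin` column.
#' @param covariates Unpenalized adjustment covariates (default age, sex).
#' @param seed Integer seed for the cross-validation folds.
#' @param ... Passed to [fit_ridge_cv()].
#' @return List with `fit` (a `ridge_fit`), `cv` (a `cv_ridge`), and
#'   `bundle` (the [build_transfer_bundle()] representation, ready to
#'   re-weight).
#' @export
fit_statin_model <- function(cohort, covariates = c("age", "sex"),
                             seed = 1L, ...) {
  d <- statin_design(cohort, covariates = covariates)
  res <- fit_ridge_cv(d$x, d$y, penalty_factors = d$penalty_factors,
                      seed = seed, ...)
  bundle <- build_transfer_bundle(
    res$fit, d$x, d$y,
    provenance = sprintf("statin model, n = %d, p = %d, cv seed = %d, flextransfer %s",
                         nrow(d$x), ncol(d$x) - length(covariates), seed,
                         as.character(packageVersion("flextransfer"))))
  list(fit = res$fit, cv = res$cv, bundle = bundle)
}
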