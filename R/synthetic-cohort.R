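#' Configuration for the synthetic lipidome cohort generator
#'
#' Defines the data regime the generator emulates: a few hundred log-normal
#' lipid species grouped into correlated classes, covariate-dependent statin
#' assignment at population prevalence, additive statin effects on log
#' concentrations (predominantly negative), and a prevalent-CVD outcome
#' driven jointly by a handful of causal lipids and statin use.
#'
#' Defaults mirror a large population cohort profiled on a targeted
#' lipidomics platform: 750 species in 30 classes, within-class correlation
#' 0.5, statin prevalence 8.4%, roughly nine in ten statin effects negative.
#'
#' @param n_samples Number of samples.
#' @param n_classes Number of lipid classes.
#' @param species_per_class Species per class (total p = classes x species).
#' @param within_class_corr Equicorrelation of log concentrations within a
#'   class, in `[0, 1)`; between-class correlation is 0.
#' @param log_mean_range Length-2 range the per-species natural-log
#'   concentration means are drawn from (concentration units arbitrary but
#'   consistent per lipid).
#' @param log_sd Per-species SD of log concentrations.
#' @param statin_prevalence_target Target population statin prevalence in
#'   (0, 1); the propensity intercept is calibrated so the expected
#'   prevalence equals it.
#' @param statin_effect_frac_negative Fraction of species whose statin
#'   effect is negative.
#' @param statin_effect_scale Half-normal scale of statin effect magnitudes
#'   on the natural-log concentration scale. 0 disables statin effects.
#' @param n_cvd_causal_lipids Number of lipid species with a direct CVD
#'   effect (`NULL`, the default, means 20 or the total species count,
#'   whichever is smaller).
#' @param cvd_effect_scale SD of the causal lipids' log-odds-per-log-unit
#'   CVD effects.
#' @param cvd_statin_beta Direct log-odds effect of statin use on prevalent
#'   CVD (negative = protective, the default; positive values construct
#'   confounding-by-indication scenarios).
#' @param cvd_prevalence_target Target prevalence of the CVD outcome.
#' @param seed Integer seed; together with the config it fully determines
#'   the generated cohort.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 1000L,
                       n_classes = 30L,
                       species_per_class = 25L,
                       within_class_corr = 0.5,
                       log_mean_range = c(-2, 3),
                       log_sd = 0.5,
                       statin_prevalence_target = 0.084,
                       statin_effect_frac_negative = 0.9,
                       statin_effect_scale = 0.3,
                       n_cvd_causal_lipids = NULL,
                       cvd_effect_scale = 0.5,
                       cvd_statin_beta = -0.5,
                       cvd_prevalence_target = 0.056,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_classes = as.integer(n_classes),
              species_per_class = as.integer(species_per_class),
              within_class_corr = within_class_corr,
              log_mean_range = as.numeric(log_mean_range),
              log_sd = log_sd,
              statin_prevalence_target = statin_prevalence_target,
              statin_effect_frac_negative = statin_effect_frac_negative,
              statin_effect_scale = statin_effect_scale,
              n_cvd_causal_lipids = as.integer(
                n_cvd_causal_lipids %||%
                  min(20L, as.integer(n_classes) * as.integer(species_per_class))),
              cvd_effect_scale = cvd_effect_scale,
              cvd_statin_beta = cvd_statin_beta,
              cvd_prevalence_target = cvd_prevalence_target,
              seed = as.integer(seed))
  stopifnot(cfg$n_samples >= 1L, cfg$n_classes >= 1L, cfg$species_per_class >= 1L)
  if (cfg$within_class_corr < 0 || cfg$within_class_corr >= 1) {
    abort("`within_class_corr` must lie in [0, 1) for a positive-definite covariance.")
  }
  if (cfg$statin_prevalence_target <= 0 || cfg$statin_prevalence_target >= 1) {
    abort("`statin_prevalence_target` must lie in (0, 1).")
  }
  if (cfg$statin_effect_frac_negative < 0 || cfg$statin_effect_frac_negative > 1) {
    abort("`statin_effect_frac_negative` must lie in [0, 1].")
  }
  if (cfg$log_sd <= 0 || cfg$statin_effect_scale < 0) {
    abort("`log_sd` must be positive and `statin_effect_scale` non-negative.")
  }
  if (length(cfg$log_mean_range) != 2L || diff(cfg$log_mean_range) < 0) {
    abort("`log_mean_range` must be an increasing length-2 interval.")
  }
  if (cfg$n_cvd_causal_lipids < 0 ||
      cfg$n_cvd_causal_lipids > cfg$n_classes * cfg$species_per_class) {
    abort("`n_cvd_causal_lipids` must be between 0 and the total species count.")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a baseline synthetic lipidomic cohort with known ground truth
#'
#' Log concentrations are drawn from a block-diagonal covariance
#' (equicorrelation `within_class_corr` within each lipid class, zero
#' between classes) and exponentiated, so every concentration is strictly
#' positive. Statin use is assigned by a logistic propensity on age and sex
#' whose intercept is calibrated to the target prevalence; statin users'
#' log concentrations are then shifted by the per-species ground-truth
#' effects. Prevalent CVD is drawn from a logistic model on the causal
#' lipids' (post-statin) log concentrations plus a direct statin term.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (a `lipid_cohort` tibble: sample_id,
#'   covariates, `statin`, `cvd`, then one column per lipid species) and
#'   `truth` (per-species `statin_deltas`, `cvd_betas`, plus the statin
#'   propensity and CVD model coefficients actually used).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    p <- config$n_classes * config$species_per_class
    lipids <- lipid_species_names(config$n_classes, config$species_per_class)

    # covariates, loosely matching adult population cohorts
    age <- rnorm(n, 51, 14)
    sex <- rbinom(n, 1, 0.55)           # 1 = female
    bmi <- rnorm(n, 27, 4.9)
    smoking <- rbinom(n, 1, 0.155)
    hypertension_med <- rbinom(n, 1, 0.15)
    diabetes <- rbinom(n, 1, 0.066)
    sbp <- rnorm(n, 130, 16)
    total_cholesterol <- rnorm(n, 5.66, 1.07)
    hdl_c <- rnorm(n, 1.43, 0.38)
    triglycerides <- exp(rnorm(n, log(1.3), 0.5))

    # ground truth statin effects: half-normal magnitudes, fixed count of
    # negative signs
    mags <- abs(rnorm(p, 0, config$statin_effect_scale))
    n_neg <- round(config$statin_effect_frac_negative * p)
    signs <- sample(rep(c(-1, 1), c(n_neg, p - n_neg)))
    statin_deltas <- setNames(mags * signs, lipids)

    # statin propensity on age and sex, intercept calibrated to target
    prop_betas <- c(age = 0.05, sex = -0.3)
    lp <- prop_betas["age"] * (age - 51) + prop_betas["sex"] * sex
    a0 <- calibrate_intercept(lp, config$statin_prevalence_target)
    statin <- rbinom(n, 1, plogis(a0 + lp))

    # block-equicorrelated log concentrations
    mu <- runif(p, config$log_mean_range[1], config$log_mean_range[2])
    rho <- config$within_class_corr
    logconc <- matrix(rnorm(n * p), n, p) * sqrt(1 - rho)
    if (rho > 0) {
      shared <- matrix(rnorm(n * config$n_classes), n, config$n_classes)
      logconc <- logconc +
        shared[, rep(seq_len(config$n_classes), each = config$species_per_class)] * sqrt(rho)
    }
    logconc <- sweep(logconc * config$log_sd, 2, mu, "+")
    logconc <- logconc + statin %*% t(statin_deltas)
    colnames(logconc) <- lipids

    # prevalent CVD from causal lipids (post-statin) plus direct statin term
    cvd_betas <- setNames(numeric(p), lipids)
    causal <- sample.int(p, config$n_cvd_causal_lipids)
    cvd_betas[causal] <- rnorm(config$n_cvd_causal_lipids, 0, config$cvd_effect_scale)
    lp_cvd <- drop(sweep(logconc[, causal, drop = FALSE], 2, mu[causal]) %*%
                     cvd_betas[causal]) + config$cvd_statin_beta * statin
    c0 <- calibrate_intercept(lp_cvd, config$cvd_prevalence_target)
    cvd <- rbinom(n, 1, plogis(c0 + lp_cvd))

    cohort <- tibble(
      sample_id = sprintf("S%05d", seq_len(n)),
      age = age, sex = sex, bmi = bmi, smoking = smoking,
      hypertension_med = hypertension_med, diabetes = diabetes, sbp = sbp,
      total_cholesterol = total_cholesterol, hdl_c = hdl_c,
      triglycerides = triglycerides, statin = statin, cvd = cvd
    )
    cohort <- dplyr::bind_cols(cohort, as_tibble(exp(logconc)))
    cohort <- new_lipid_cohort(cohort, lipids, log_scale = FALSE)

    truth <- list(
      statin_deltas = statin_deltas,
      cvd_betas = cvd_betas,
      statin_assignment_betas = c(`(Intercept)` = unname(a0), prop_betas),
      cvd_model = c(`(Intercept)` = unname(c0), statin = config$cvd_statin_beta),
      log_means = setNames(mu, lipids)
    )
    list(cohort = cohort, truth = truth)
  })
}

#' Generate follow-up concentrations for an existing cohort
#'
#' Emulates a trial with baseline and 12-month samples: follow-up log
#' concentration = baseline log concentration + ground-truth statin effect
#' x post-randomization statin status + Gaussian noise. Follow-up clinical
#' lipids respond to treatment (total cholesterol and triglycerides fall,
#' HDL-C rises slightly).
#'
#' @param cohort A baseline `lipid_cohort` (concentration scale).
#' @param truth Ground truth from [simulate_cohort()].
#' @param noise_sd SD of follow-up noise on the log scale.
#' @param seed Integer seed.
#' @param statin Post-randomization statin assignment (0/1, one per
#'   sample); defaults to the cohort's `statin` column.
#' @return A `lipid_cohort` of follow-up measurements with the same lipid
#'   names and sample ids; its `statin` column is the assignment used.
#' @export
simulate_followup <- function(cohort, truth, noise_sd, seed = 1L,
                              statin = NULL) {
  check_lipid_cohort(cohort, log_scale = FALSE)
  if (isTRUE(attr(cohort, "followup"))) abort("Cohort already is a follow-up table.")
  lipids <- lipid_names(cohort)
  if (!identical(lipids, names(truth$statin_deltas))) {
    abort("Lipid names of `cohort` and `truth$statin_deltas` do not match.")
  }
  statin <- statin %||% cohort$statin
  if (length(statin) != nrow(cohort) || !all(statin %in% c(0, 1))) {
    abort("`statin` must be a 0/1 vector with one entry per sample.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  with_seed(seed, {
    n <- nrow(cohort)
    p <- length(lipids)
    logfu <- log(lipid_matrix(cohort)) + statin %*% t(truth$statin_deltas) +
      matrix(rnorm(n * p, 0, noise_sd), n, p)
    fu <- cohort
    fu[lipids] <- as_tibble(exp(logfu))
    fu$statin <- as.integer(statin)
    fu$total_cholesterol <- cohort$total_cholesterol *
      exp(-0.25 * statin + rnorm(n, 0, noise_sd / 2))
    fu$hdl_c <- cohort$hdl_c * exp(0.03 * statin + rnorm(n, 0, noise_sd / 2))
    fu$triglycerides <- cohort$triglycerides *
      exp(-0.12 * statin + rnorm(n, 0, noise_sd / 2))
    fu <- new_lipid_cohort(fu, lipids, log_scale = FALSE)
    attr(fu, "followup") <- TRUE
    fu
  })
}

#' Simulate quality-control replicate measurements of a reference material
#'
#' Each replicate is `reference * scale_factor * lognormal noise` with
#' coefficient of variation `cv` (median-unbiased: the log-noise mean is 0,
#' so per-lipid replicate medians estimate `reference * scale_factor`).
#' Used to emulate pooled reference-plasma injections interspersed with
#' cohort samples.
#'
#' @param reference Per-lipid positive reference concentrations (named).
#' @param scale_factors Per-lipid positive measurement scale distortions.
#' @param n_reps Number of replicates (rows).
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return `n_reps` x `length(reference)` matrix of positive values.
#' @export
simulate_qc_replicates <- function(reference, scale_factors, n_reps, cv,
                                   seed = 1L) {
  if (length(reference) != length(scale_factors)) {
    abort("`reference` and `scale_factors` must have the same length.")
  }
  if (any(reference <= 0) || any(scale_factors <= 0)) {
    abort("Reference concentrations and scale factors must be positive.")
  }
  if (n_reps < 1L) abort("`n_reps` must be at least 1.")
  if (cv < 0) abort("`cv` must be non-negative.")
  with_seed(seed, {
    p <- length(reference)
    sdlog <- sqrt(log(1 + cv^2))
    noise <- matrix(exp(rnorm(n_reps * p, 0, sdlog)), n_reps, p)
    out <- sweep(noise, 2, reference * scale_factors, "*")
    colnames(out) <- names(reference)
    out
  })
}

# ---- lipid_cohort helpers --------------------------------------------------

#' Mark a data frame as a lipid cohort table
#'
#' Tags which columns are lipid species (everything else is metadata:
#' covariates and outcomes) and whether concentrations are on the natural-log
#' scale. Row subsetting with `[` drops the tag, so re-apply after slicing.
#'
#' @param tbl A data frame / tibble with a `sample_id` column.
#' @param lipids Character vector of the lipid species columns.
#' @param log_scale Are the lipid columns natural-log concentrations?
#' @return A `lipid_cohort` tibble.
#' @export
as_lipid_cohort <- function(tbl, lipids, log_scale = FALSE) {
  tbl <- as_tibble(tbl)
  if (!"sample_id" %in% names(tbl)) abort("`tbl` needs a `sample_id` column.")
  miss <- setdiff(lipids, names(tbl))
  if (length(miss) > 0) {
    abort(paste0("Lipid columns not in `tbl`: ", paste(head(miss, 5), collapse = ", ")))
  }
  new_lipid_cohort(tbl, lipids, log_scale = log_scale)
}

new_lipid_cohort <- function(tbl, lipids, log_scale = FALSE) {
  stopifnot(all(lipids %in% names(tbl)))
  attr(tbl, "lipid_names") <- lipids
  attr(tbl, "log_scale") <- log_scale
  class(tbl) <- unique(c("lipid_cohort", class(tbl)))
  tbl
}

#' Lipid species columns of a cohort table
#'
#' @param cohort A `lipid_cohort`.
#' @return `lipid_names()`: character vector of lipid column names;
#'   `lipid_matrix()`: the samples x lipids numeric matrix.
#' @export
lipid_names <- function(cohort) {
  ln <- attr(cohort, "lipid_names")
  if (is.null(ln)) abort("Not a lipid_cohort: no `lipid_names` attribute.")
  ln
}

#' @rdname lipid_names
#' @export
lipid_matrix <- function(cohort) {
  m <- as.matrix(cohort[lipid_names(cohort)])
  rownames(m) <- cohort$sample_id
  m
}

check_lipid_cohort <- function(cohort, log_scale = NULL) {
  if (!inherits(cohort, "lipid_cohort")) abort("Expected a `lipid_cohort` table.")
  if (!is.null(log_scale) && !identical(attr(cohort, "log_scale"), log_scale)) {
    abort(if (log_scale) {
      "This operation expects log-transformed concentrations; run log_transform() first."
    } else {
      "This operation expects raw (not log-transformed) concentrations."
    })
  }
  invisible(cohort)
}

lipid_species_names <- function(n_classes, species_per_class) {
  as.vector(vapply(seq_len(n_classes), function(k) {
    sprintf("class%02d_sp%02d", k, seq_len(species_per_class))
  }, character(species_per_class)))
}

# choose intercept a0 so mean(plogis(a0 + lp)) equals the target prevalence
calibrate_intercept <- function(lp, target) {
  uniroot(function(a) mean(plogis(a + lp)) - target,
          lower = -30, upper = 30, tol = 1e-10)$root
}
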