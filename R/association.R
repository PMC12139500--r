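#' Per-lipid statin-effect scan on paired baseline / follow-up data
#'
#' For each lipid species, fits an OLS model of the log follow-up
#' concentration on statin usage, the log baseline concentration, their
#' interaction, and covariates (age, sex, BMI, hypertension medication,
#' diabetes, smoking, systolic blood pressure) plus clinical lipids (total
#' cholesterol, HDL-C, triglycerides) — from baseline by default, or from
#' the 12-month follow-up when `adjust_followup_clinical = TRUE` (isolating
#' statin effects on lipid metabolism from the bulk lipoprotein change).
#' Only samples present in both tables are used. The statin main effects
#' and the statin x baseline interactions are each corrected by
#' Benjamini-Hochberg as their own family.
#'
#' @param baseline,followup `lipid_cohort` tables on the concentration
#'   scale, sharing lipid names; `followup$statin` is the
#'   post-randomization treatment indicator.
#' @param adjust_followup_clinical Use follow-up instead of baseline
#'   clinical lipids as adjustment covariates.
#' @return Tibble with one row per (lipid, term): `lipid`, `term`
#'   (`"statin"` or `"statin:baseline"`), `beta`, `se`, `p`, `q`,
#'   `model_tag`. Lipids whose per-lipid design is rank deficient are
#'   reported with `NA` estimates and `skipped = TRUE`.
#' @export
statin_effect_scan <- function(baseline, followup,
                               adjust_followup_clinical = FALSE) {
  check_lipid_cohort(baseline, log_scale = FALSE)
  check_lipid_cohort(followup, log_scale = FALSE)
  lipids <- intersect(lipid_names(baseline), lipid_names(followup))
  if (length(lipids) == 0L) abort("No shared lipid species.")
  ids <- intersect(baseline$sample_id, followup$sample_id)
  if (length(ids) == 0L) abort("No paired samples: baseline and follow-up share no sample ids.")
  b <- baseline[match(ids, baseline$sample_id), ]
  f <- followup[match(ids, followup$sample_id), ]

  covars <- data.frame(
    statin = f$statin,
    age = b$age, sex = b$sex, bmi = b$bmi,
    hypertension_med = b$hypertension_med, diabetes = b$diabetes,
    smoking = b$smoking, sbp = b$sbp)
  if (adjust_followup_clinical) {
    covars$total_cholesterol <- f$total_cholesterol
    covars$hdl_c <- f$hdl_c
    covars$triglycerides <- f$triglycerides
    tag <- "clinical12m_adjusted"
  } else {
    covars$total_cholesterol <- b$total_cholesterol
    covars$hdl_c <- b$hdl_c
    covars$triglycerides <- b$triglycerides
    tag <- "baseline_adjusted"
  }
  if (anyNA(covars)) abort("Covariates contain missing values.")

  logb <- log(lipid_matrix(b)[, lipids, drop = FALSE])
  logf <- log(lipid_matrix(f)[, lipids, drop = FALSE])

  rows <- purrr::map(lipids, function(l) {
    d <- covars
    d$baseline <- logb[, l]
    d$interaction <- d$statin * d$baseline
    res <- tryCatch(ols_with_stats(d, logf[, l]), error = function(e) NULL)
    if (is.null(res)) {
      return(tibble(lipid = l, term = c("statin", "statin:baseline"),
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    skipped = TRUE))
    }
    keep <- res$term %in% c("statin", "interaction")
    tibble(lipid = l,
           term = c("statin", "statin:baseline"),
           beta = res$estimate[keep],
           se = res$std_error[keep],
           p = res$p_value[keep],
           skipped = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  n_skip <- sum(out$skipped) / 2
  if (n_skip > 0) {
    warn(sprintf("%d lipid(s) skipped due to rank-deficient designs.", n_skip))
  }
  out <- out |>
    dplyr::group_by(.data$term) |>
    dplyr::mutate(q = bh_adjust_na(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(model_tag = tag) |>
    dplyr::select("lipid", "term", "beta", "se", "p", "q", "model_tag", "skipped")
  out
}

#' Per-lipid prevalent-CVD association scan
#'
#' For each lipid species, fits an unpenalized logistic regression of
#' prevalent CVD on the log lipid concentration plus covariates (age, sex,
#' BMI, hypertension medication, diabetes, smoking, systolic blood
#' pressure), optionally adding statin usage as a covariate. Comparing the
#' two variants exposes the confounding that statin use introduces into
#' lipid-disease associations. Effects are log odds ratios per log-unit
#' concentration; q by Benjamini-Hochberg across lipids.
#'
#' @param cohort A log-transformed `lipid_cohort` with a binary `cvd`
#'   column.
#' @param adjust_statin Include statin usage as a covariate.
#' @return Tibble: `lipid`, `beta` (log OR), `se`, `p`, `q`, `model_tag`,
#'   `separation` flag.
#' @export
cvd_assoc_scan <- function(cohort, adjust_statin = TRUE) {
  check_lipid_cohort(cohort, log_scale = TRUE)
  if (length(unique(cohort$cvd)) < 2L) abort("Both CVD classes must be present.")
  lipids <- lipid_names(cohort)
  covars <- data.frame(age = cohort$age, sex = cohort$sex, bmi = cohort$bmi,
                       hypertension_med = cohort$hypertension_med,
                       diabetes = cohort$diabetes, smoking = cohort$smoking,
                       sbp = cohort$sbp)
  if (adjust_statin) covars$statin <- cohort$statin
  tag <- if (adjust_statin) "statin_adjusted" else "unadjusted"
  m <- lipid_matrix(cohort)

  rows <- purrr::map(lipids, function(l) {
    d <- cbind(data.frame(lipid = m[, l]), covars)
    res <- suppressWarnings(logistic_with_stats(d, cohort$cvd))
    i <- match("lipid", res$term)
    tibble(lipid = l, beta = res$estimate[i], se = res$std_error[i],
           p = res$p_value[i], separation = attr(res, "separation"))
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(q = bh_adjust(.data$p), model_tag = tag) |>
    dplyr::select("lipid", "beta", "se", "p", "q", "model_tag", "separation")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity
#' (wraps [stats::p.adjust()] with input validation). The field sometimes
#' reports Storey q-values instead; this package uses Benjamini-Hochberg
#' throughout.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    abort("`p_values` must be numeric in [0, 1] with no missing values.")
  }
  p.adjust(p_values, method = "BH")
}

# BH over the non-missing entries (skipped lipids keep NA)
bh_adjust_na <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) q[ok] <- bh_adjust(p[ok])
  q
}

#' Significance classes and adjusted-vs-unadjusted cross-tabulation
#'
#' Classifies every lipid in each model into three tiers — corrected
#' p < alpha (`q < alpha`), nominal only (`p < alpha` but `q >= alpha`),
#' or non-significant — and cross-tabulates the unadjusted against the
#' adjusted classification. The off-diagonal counts are the lipids whose
#' apparent disease association is created or masked by statin confounding.
#'
#' @param unadjusted,adjusted Association tables over the same lipid set
#'   (from [cvd_assoc_scan()] or any table with `lipid`, `p`, `q` columns).
#' @param alpha Significance level (default 0.05).
#' @return List with `classes` (tibble: lipid, class_unadjusted,
#'   class_adjusted), `crosstab` (3 x 3 matrix, unadjusted rows x adjusted
#'   columns), `n_consistent` and `n_changed`.
#' @export
classify_and_crosstab <- function(unadjusted, adjusted, alpha = 0.05) {
  if (!setequal(unadjusted$lipid, adjusted$lipid) ||
      nrow(unadjusted) != nrow(adjusted)) {
    abort("`unadjusted` and `adjusted` must cover the same lipid set.")
  }
  adjusted <- adjusted[match(unadjusted$lipid, adjusted$lipid), ]
  lv <- c("corrected_p_lt_0.05", "p_lt_0.05", "p_ge_0.05")
  cls <- function(p, q) {
    factor(ifelse(q < alpha, lv[1], ifelse(p < alpha, lv[2], lv[3])), levels = lv)
  }
  cu <- cls(unadjusted$p, unadjusted$q)
  ca <- cls(adjusted$p, adjusted$q)
  tab <- table(unadjusted = cu, adjusted = ca)
  list(
    classes = tibble(lipid = unadjusted$lipid,
                     class_unadjusted = as.character(cu),
                     class_adjusted = as.character(ca)),
    crosstab = unclass(tab),
    n_consistent = sum(diag(tab)),
    n_changed = sum(tab) - sum(diag(tab))
  )
}
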