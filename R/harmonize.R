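#' Reference panel constructor
#'
#' A consensus reference-concentration panel (for example, pooled reference
#' plasma measured across many studies): one positive concentration per
#' lipid species. Used as the anchor for cross-cohort harmonization.
#'
#' @param lipid Character vector of unique lipid names.
#' @param concentration Positive consensus concentrations, same length.
#' @return A `reference_panel` tibble with columns `lipid`, `concentration`.
#' @export
reference_panel <- function(lipid, concentration) {
  lipid <- as.character(lipid)
  if (anyDuplicated(lipid)) abort("Reference panel lipid names must be unique.")
  if (length(concentration) != length(lipid) || any(!is.finite(concentration)) ||
      any(concentration <= 0)) {
    abort("Reference concentrations must be positive and match the lipid names.")
  }
  structure(tibble(lipid = lipid, concentration = as.numeric(concentration)),
            class = c("reference_panel", class(tibble())))
}

#' Correction factors from reference-material QC replicates
#'
#' For every lipid measured in both the panel and the cohort's QC
#' replicates, the correction factor is the ratio of the reference-point
#' concentration to the median concentration measured in that cohort's QC
#' replicates. Multiplying cohort concentrations by the factor aligns the
#' cohort's QC medians with the panel.
#'
#' @param panel A [reference_panel()].
#' @param cohort_qc Replicates x lipids matrix of the cohort's QC
#'   measurements (named columns).
#' @return A `correction_factors` tibble: `lipid`, `factor`, `method`
#'   (`"qc_ratio"`), `n_used` (replicate count). Cohort QC lipids absent
#'   from the panel are flagged in the `unmatched_lipids` attribute and get
#'   no factor.
#' @export
qc_correction_factors <- function(panel, cohort_qc) {
  stopifnot(inherits(panel, "reference_panel"))
  if (!is.matrix(cohort_qc) || is.null(colnames(cohort_qc))) {
    abort("`cohort_qc` must be a replicates x lipids matrix with named columns.")
  }
  if (nrow(cohort_qc) < 1L) abort("At least one QC replicate is required.")
  common <- intersect(colnames(cohort_qc), panel$lipid)
  if (length(common) == 0L) abort("No lipid overlap between the panel and the QC matrix.")
  unmatched <- setdiff(colnames(cohort_qc), panel$lipid)
  if (length(unmatched) > 0) {
    inform(sprintf("%d QC lipid(s) absent from the reference panel get no factor.",
                   length(unmatched)))
  }
  med <- apply(cohort_qc[, common, drop = FALSE], 2, median)
  if (any(!is.finite(med)) || any(med <= 0)) {
    bad <- common[!is.finite(med) | med <= 0]
    abort(paste0("Non-positive QC medians for: ", paste(head(bad, 5), collapse = ", ")))
  }
  ref <- setNames(panel$concentration, panel$lipid)[common]
  out <- tibble(lipid = common, factor = unname(ref / med),
                method = "qc_ratio", n_used = nrow(cohort_qc))
  structure(out, unmatched_lipids = unmatched,
            class = c("correction_factors", class(out)))
}

#' Correction factors from covariate-matched sub-cohorts
#'
#' When a cohort has no reference-material QC measurements, factors are
#' derived by matching it to an already-harmonized reference cohort:
#' 1:1 nearest-neighbor matching without replacement on standardized
#' matching covariates (Euclidean distance, globally greedy: closest pair
#' first), then per lipid the ratio of the reference sub-cohort median to
#' the target sub-cohort median.
#'
#' @param reference_cohort,target_cohort `lipid_cohort` tables on the
#'   concentration scale; the factor re-scales the target onto the
#'   reference.
#' @param matching_covariates Covariate columns used for matching (present
#'   in both cohorts).
#' @param n_pairs Number of matched pairs to form.
#' @param seed Integer seed (kept for interface stability; the greedy
#'   matching itself is deterministic, ties broken by sample order).
#' @return A `correction_factors` tibble (`method = "matched_subcohort"`,
#'   `n_used` = pair count), with the matched index pairs in the
#'   `matched_pairs` attribute.
#' @export
matched_subcohort_factors <- function(reference_cohort, target_cohort,
                                      matching_covariates, n_pairs,
                                      seed = 1L) {
  check_lipid_cohort(reference_cohort, log_scale = FALSE)
  check_lipid_cohort(target_cohort, log_scale = FALSE)
  miss_r <- setdiff(matching_covariates, names(reference_cohort))
  miss_t <- setdiff(matching_covariates, names(target_cohort))
  if (length(miss_r) + length(miss_t) > 0) {
    abort(paste0("Matching covariates missing: ",
                 paste(unique(c(miss_r, miss_t)), collapse = ", ")))
  }
  if (n_pairs > min(nrow(reference_cohort), nrow(target_cohort))) {
    abort("`n_pairs` exceeds the size of one of the cohorts.")
  }
  common <- intersect(lipid_names(reference_cohort), lipid_names(target_cohort))
  if (length(common) == 0L) abort("No lipid overlap between the cohorts.")

  # standardize covariates on the pooled distribution
  cr <- as.matrix(reference_cohort[matching_covariates])
  ct <- as.matrix(target_cohort[matching_covariates])
  pooled <- rbind(cr, ct)
  ctr <- colMeans(pooled)
  scl <- apply(pooled, 2, sd)
  scl[scl == 0] <- 1
  zr <- sweep(sweep(cr, 2, ctr), 2, scl, "/")
  zt <- sweep(sweep(ct, 2, ctr), 2, scl, "/")

  pairs <- greedy_nn_match(zr, zt, n_pairs)
  ref_sub <- lipid_matrix(reference_cohort)[pairs$reference, common, drop = FALSE]
  tgt_sub <- lipid_matrix(target_cohort)[pairs$target, common, drop = FALSE]
  fac <- apply(ref_sub, 2, median) / apply(tgt_sub, 2, median)

  out <- tibble(lipid = common, factor = unname(fac),
                method = "matched_subcohort", n_used = n_pairs)
  structure(out, matched_pairs = pairs,
            class = c("correction_factors", class(out)))
}

#' Apply correction factors to a cohort's concentrations
#'
#' Each lipid with a factor is multiplied by it; lipids without a factor
#' pass through unchanged with a warning. The applied factors are recorded
#' in the `applied_factors` attribute.
#'
#' @param cohort A `lipid_cohort` on the concentration scale.
#' @param factors A `correction_factors` table.
#' @return The corrected `lipid_cohort`.
#' @export
apply_factors <- function(cohort, factors) {
  check_lipid_cohort(cohort, log_scale = FALSE)
  stopifnot(inherits(factors, "correction_factors") || is.data.frame(factors))
  lipids <- lipid_names(cohort)
  fac <- setNames(factors$factor, factors$lipid)
  missing_fac <- setdiff(lipids, names(fac))
  if (length(missing_fac) > 0) {
    warn(sprintf("%d lipid(s) have no correction factor and pass through unchanged.",
                 length(missing_fac)))
  }
  use <- intersect(lipids, names(fac))
  for (l in use) cohort[[l]] <- cohort[[l]] * fac[[l]]
  attr(cohort, "applied_factors") <- fac[use]
  cohort
}

#' Natural-log transform of a cohort's concentrations
#'
#' Lipidomic concentration data are log-transformed before statistical
#' analysis. Zeros are handled per `zero_policy`: `"half_min"` (default)
#' replaces each zero with half the smallest positive value of that lipid
#' (reported per lipid); `"error"` fails, naming the sample and lipid.
#' Negative concentrations are always an error.
#'
#' @param cohort A `lipid_cohort` on the concentration scale.
#' @param zero_policy `"half_min"` or `"error"`.
#' @return The `lipid_cohort` with natural-log concentrations
#'   (`log_scale` attribute set).
#' @export
log_transform <- function(cohort, zero_policy = c("half_min", "error")) {
  check_lipid_cohort(cohort, log_scale = FALSE)
  zero_policy <- match.arg(zero_policy)
  lipids <- lipid_names(cohort)
  m <- lipid_matrix(cohort)
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Negative concentration at sample %s, lipid %s.",
                  rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  zero_cols <- colnames(m)[colSums(m == 0) > 0]
  if (length(zero_cols) > 0) {
    if (zero_policy == "error") {
      idx <- which(m == 0, arr.ind = TRUE)[1, ]
      abort(sprintf("Zero concentration at sample %s, lipid %s (zero_policy = 'error').",
                    rownames(m)[idx[1]], colnames(m)[idx[2]]))
    }
    for (l in zero_cols) {
      pos <- m[, l][m[, l] > 0]
      if (length(pos) == 0L) {
        abort(sprintf("Lipid %s is zero in every sample; cannot impute half-minimum.", l))
      }
      m[m[, l] == 0, l] <- min(pos) / 2
    }
    inform(sprintf("Replaced zeros with half the minimum positive value in %d lipid(s): %s",
                   length(zero_cols), paste(head(zero_cols, 5), collapse = ", ")))
  }
  cohort[lipids] <- as_tibble(log(m))
  attr(cohort, "log_scale") <- TRUE
  cohort
}

# globally greedy 1:1 nearest-neighbor matching without replacement:
# repeatedly link the closest remaining (reference, target) pair.
greedy_nn_match <- function(zr, zt, n_pairs) {
  d <- outer(rowSums(zr^2), rowSums(zt^2), "+") - 2 * tcrossprod(zr, zt)
  d[d < 0] <- 0  # numerical negatives
  ref_idx <- integer(n_pairs)
  tgt_idx <- integer(n_pairs)
  dists <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    best <- arrayInd(which.min(d), dim(d))
    ref_idx[k] <- best[1]
    tgt_idx[k] <- best[2]
    dists[k] <- sqrt(d[best])
    d[best[1], ] <- Inf
    d[, best[2]] <- Inf
  }
  list(reference = ref_idx, target = tgt_idx, distance = dists)
}
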