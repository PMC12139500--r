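#' Read a cohort from delimited text files
#'
#' `concentrations_path` holds `sample_id` plus one numeric column per
#' lipid species; `metadata_path` holds `sample_id` plus covariates and
#' outcome columns. The two are inner-joined on `sample_id`; dropped rows
#' are counted and reported. Lipid-name whitespace is trimmed; duplicate
#' lipid names are fatal; malformed numeric cells are rejected (never
#' coerced), with their location reported.
#'
#' @param concentrations_path,metadata_path CSV file paths.
#' @param required_covariates Metadata columns that must be present.
#' @return A `lipid_cohort` tibble (concentration scale).
#' @export
read_cohort <- function(concentrations_path, metadata_path,
                        required_covariates = c("age", "sex")) {
  conc <- readr::read_csv(concentrations_path, show_col_types = FALSE,
                          progress = FALSE, name_repair = "minimal")
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  for (d in list(conc, meta)) {
    if (!"sample_id" %in% names(d)) abort("Both files need a `sample_id` column.")
  }
  names(conc) <- trimws(names(conc))
  lipids <- names(conc)[names(conc) != "sample_id"]
  dup <- lipids[duplicated(lipids)]
  if (length(dup) > 0) {
    abort(paste0("Duplicated lipid column(s): ", paste(unique(dup), collapse = ", ")))
  }
  for (l in lipids) {
    if (!is.numeric(conc[[l]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(conc[[l]]))))[1]
      abort(sprintf("Non-numeric concentration in lipid '%s', row %d ('%s').",
                    l, bad, as.character(conc[[l]][bad])))
    }
  }
  miss <- setdiff(required_covariates, names(meta))
  if (length(miss) > 0) {
    abort(paste0("Metadata is missing required covariate(s): ",
                 paste(miss, collapse = ", ")))
  }
  conc$sample_id <- as.character(conc$sample_id)
  meta$sample_id <- as.character(meta$sample_id)
  joined <- dplyr::inner_join(meta, conc, by = "sample_id")
  n_drop <- (nrow(conc) - nrow(joined)) + (nrow(meta) - nrow(joined))
  if (n_drop > 0) {
    inform(sprintf("Dropped %d unmatched row(s) in the sample_id inner join.", n_drop))
  }
  if (nrow(joined) == 0L) abort("No samples shared between the two files.")
  new_lipid_cohort(joined, lipids, log_scale = FALSE)
}

#' Write a cohort to delimited text files
#'
#' Writes `concentrations.csv` (sample_id + lipids) and `metadata.csv`
#' (sample_id + covariates/outcomes) into `dir`.
#'
#' @param cohort A `lipid_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  check_lipid_cohort(cohort)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lipids <- lipid_names(cohort)
  cp <- file.path(dir, "concentrations.csv")
  mp <- file.path(dir, "metadata.csv")
  readr::write_csv(cohort[c("sample_id", lipids)], cp, progress = FALSE)
  readr::write_csv(cohort[setdiff(names(cohort), lipids)], mp, progress = FALSE)
  invisible(c(concentrations = cp, metadata = mp))
}

#' Read / write a reference panel or correction factors
#'
#' Two-column delimited text: `lipid`, then `concentration` (panel) or
#' `factor` (correction factors).
#'
#' @param path CSV file path.
#' @param panel,factors Object to write.
#' @return The read object, or (for writers) the path invisibly.
#' @export
read_reference_panel <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("lipid", "concentration") %in% names(d))) {
    abort("Reference panel file needs `lipid` and `concentration` columns.")
  }
  reference_panel(d$lipid, d$concentration)
}

#' @rdname read_reference_panel
#' @export
write_reference_panel <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  readr::write_csv(as_tibble(panel), path, progress = FALSE)
  invisible(path)
}

#' @rdname read_reference_panel
#' @export
read_correction_factors <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("lipid", "factor") %in% names(d))) {
    abort("Correction factor file needs `lipid` and `factor` columns.")
  }
  if (any(!is.finite(d$factor)) || any(d$factor <= 0)) {
    abort("Correction factors must be positive and finite.")
  }
  if (!"method" %in% names(d)) d$method <- "unknown"
  if (!"n_used" %in% names(d)) d$n_used <- NA_integer_
  structure(as_tibble(d), class = c("correction_factors", class(tibble())))
}

#' @rdname read_reference_panel
#' @export
write_correction_factors <- function(factors, path) {
  readr::write_csv(as_tibble(factors), path, progress = FALSE)
  invisible(path)
}

#' Save / load generator ground truth as JSON
#'
#' @param truth Ground-truth list from [simulate_cohort()].
#' @param path JSON file path.
#' @return The truth list, or the path invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$statin_deltas <- unlist(x$statin_deltas)
  x$cvd_betas <- unlist(x$cvd_betas)
  x$statin_assignment_betas <- unlist(x$statin_assignment_betas)
  x
}

#' Serialize a ridge fit to JSON
#'
#' Stores names, intercept, coefficients, lambda, scaling, penalty factors
#' and convergence metadata. Numbers are written at full precision.
#'
#' @param fit A `ridge_fit`.
#' @param path JSON file path.
#' @return The fit, or the path invisibly.
#' @export
write_ridge_fit <- function(fit, path) {
  stopifnot(inherits(fit, "ridge_fit"))
  payload <- list(
    predictor_names = fit$design$predictor_names,
    beta0 = fit$beta0,
    betas = unname(fit$betas),
    beta_std = unname(fit$beta_std),
    lambda = fit$lambda,
    center = unname(fit$scaling$center),
    scale = unname(fit$scaling$scale),
    penalty_factors = unname(fit$design$penalty_factors),
    standardize = fit$design$standardize,
    converged = fit$converged,
    n_iter = fit$n_iter,
    final_deviance = fit$final_deviance,
    reweighted = isTRUE(fit$reweighted),
    package_version = as.character(packageVersion("flextransfer"))
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_ridge_fit
#' @export
read_ridge_fit <- function(path) {
  p <- jsonlite::fromJSON(path)
  vars <- p$predictor_names
  structure(list(
    beta0 = p$beta0,
    betas = setNames(p$betas, vars),
    beta_std = setNames(p$beta_std, c("(Intercept)", vars)),
    lambda = p$lambda,
    scaling = list(center = setNames(p$center, vars),
                   scale = setNames(p$scale, vars)),
    design = list(predictor_names = vars,
                  penalty_factors = setNames(p$penalty_factors, vars),
                  standardize = p$standardize, intercept = TRUE),
    converged = p$converged,
    n_iter = p$n_iter,
    final_deviance = p$final_deviance,
    grad_inf = NA_real_,
    fitted = NULL,
    n = NA_integer_,
    reweighted = isTRUE(p$reweighted)
  ), class = "ridge_fit")
}
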