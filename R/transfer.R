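#' Build a portable transfer bundle from a fitted ridge-logistic model
#'
#' Represents a converged fit as the pair of transfer matrices
#' \deqn{M = X^T W X + n \lambda P, \qquad \upsilon = X^T W z_w,}
#' computed on the standardized design with intercept column, where
#' \eqn{W_{ii} = p_i(1 - p_i)} at the converged probabilities,
#' \eqn{P = \mathrm{diag}(\phi)} holds the penalty factors (0 for the
#' intercept and unpenalized adjustment covariates), and
#' \eqn{z_w = X\hat\beta + W^{-1}(y - p)} is the converged IRLS working
#' response. At a penalized-IRLS fixed point
#' \eqn{X^T W z_w = (X^T W X + n\lambda P)\hat\beta}, so
#' \eqn{M^{-1}\upsilon} reproduces the converged standardized coefficients
#' exactly — re-weighting to a predictor subset via [reweight()] then needs
#' only the bundle, never the individual-level data.
#'
#' With no penalty (`lambda = 0`) the working response and the fitted log
#' odds \eqn{z = \mathrm{logit}(p)} give the same \eqn{\upsilon}, because
#' the unpenalized score equation \eqn{X^T(y - p) = 0} holds at the MLE.
#' Under a ridge penalty only the working-response form preserves the
#' full-set identity, so that is what is stored; `M` likewise carries the
#' penalty term so subset re-estimation inherits the same regularization.
#'
#' @param fit A converged [fit_ridge_logistic()] result.
#' @param x,y The training predictors and outcome the fit was computed on.
#' @param provenance Free-text metadata recorded in the bundle (training
#'   description, seed, and so on).
#' @return A `transfer_bundle`: variable names (intercept first), `M`, `v`,
#'   `lambda`, penalty factors, per-variable scaling, the non-droppable
#'   variable set (`always_keep`: intercept plus unpenalized covariates),
#'   and provenance.
#' @export
build_transfer_bundle <- function(fit, x, y, provenance = "") {
  stopifnot(inherits(fit, "ridge_fit"))
  if (!fit$converged) {
    abort("The fit did not converge; transfer matrices require a converged fit.")
  }
  x <- as_design_matrix(x)
  y <- check_binary_outcome(y, n = nrow(x))
  if (!identical(colnames(x), fit$design$predictor_names)) {
    abort("Columns of `x` must match the fit's predictors exactly (name and order).")
  }
  n <- nrow(x)
  ctr <- fit$scaling$center
  scl <- fit$scaling$scale
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  Xs <- cbind(`(Intercept)` = 1, xs)
  beta <- fit$beta_std
  eta <- drop(Xs %*% beta)
  p <- pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
  w <- p * (1 - p)
  pf <- c(0, unname(fit$design$penalty_factors))

  M <- crossprod(Xs, Xs * w)
  diag(M) <- diag(M) + n * fit$lambda * pf
  zw <- eta + (y - p) / w
  v <- drop(crossprod(Xs, w * zw))

  beta_rec <- tryCatch(drop(chol2inv_solve(M, v)), error = function(e) {
    ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    abort(sprintf("Transfer matrix M is singular (smallest eigenvalue %.3g).", ev))
  })
  err <- max(abs(beta_rec - beta))
  if (err > 1e-8) {
    warn(sprintf("Full-set reconstruction residual %.3g exceeds 1e-8; the fit may be under-converged.", err))
  }

  vars <- colnames(Xs)
  structure(list(
    variable_names = vars,
    M = M,
    v = setNames(v, vars),
    lambda = fit$lambda,
    penalty_factors = setNames(pf, vars),
    scaling = list(center = setNames(c(0, unname(ctr)), vars),
                   scale = setNames(c(1, unname(scl)), vars)),
    always_keep = vars[pf == 0],
    n_train = n,
    format_version = "1.0",
    provenance = provenance
  ), class = "transfer_bundle")
}

#' Re-estimate coefficients for a predictor subset without refitting
#'
#' Extracts the submatrix \eqn{M_{J,J}} and subvector \eqn{\upsilon_J} for
#' the requested variable subset and solves
#' \eqn{\hat\beta_{reduced} = M_{J,J}^{-1} \upsilon_J} by a symmetric
#' positive-definite factorization (never an explicit inverse). The
#' intercept and the bundle's `always_keep` covariates must be retained;
#' only penalized predictors (lipid species) may be dropped. The result is
#' a regular `ridge_fit` over the subset, usable directly with
#' [predict_proba()] — no individual-level data is consumed.
#'
#' If \eqn{M_{J,J}} is numerically singular (condition number above 1e12)
#' the solve falls back to least squares and the returned fit carries
#' `solve_fallback = TRUE` with a warning.
#'
#' @param bundle A [build_transfer_bundle()] result.
#' @param variables Character vector of retained predictor names (the
#'   intercept is implicit and always kept).
#' @return A `ridge_fit` over `variables`, coefficients on the input scale.
#' @export
reweight <- function(bundle, variables) {
  stopifnot(inherits(bundle, "transfer_bundle"))
  variables <- unique(as.character(variables))
  all_vars <- bundle$variable_names
  J <- union("(Intercept)", variables)
  unknown <- setdiff(J, all_vars)
  if (length(unknown) > 0) {
    abort(paste0("Unknown variables: ", paste(head(unknown, 5), collapse = ", ")))
  }
  missing_keep <- setdiff(bundle$always_keep, J)
  if (length(missing_keep) > 0) {
    abort(paste0("Non-droppable variables must be retained: ",
                 paste(missing_keep, collapse = ", ")))
  }
  J <- all_vars[all_vars %in% J]   # bundle order, intercept first

  MJ <- bundle$M[J, J, drop = FALSE]
  vJ <- bundle$v[J]
  fallback <- FALSE
  beta_std <- tryCatch(drop(chol2inv_solve(MJ, vJ)), error = function(e) NULL)
  if (!is.null(beta_std)) {
    kp <- kappa(MJ, exact = FALSE)
    if (!is.finite(kp) || kp > 1e12) beta_std <- NULL
  }
  if (is.null(beta_std)) {
    kp <- tryCatch(kappa(MJ, exact = TRUE), error = function(e) NA_real_)
    warn(sprintf(
      "M[J,J] is numerically singular (condition number %.3g); using a least-squares solve.", kp))
    beta_std <- drop(qr.solve(MJ, vJ, tol = 1e-300))
    fallback <- TRUE
  }
  names(beta_std) <- J

  pred <- setdiff(J, "(Intercept)")
  ctr <- bundle$scaling$center[pred]
  scl <- bundle$scaling$scale[pred]
  betas <- beta_std[pred] / scl
  beta0 <- beta_std[["(Intercept)"]] - sum(beta_std[pred] * ctr / scl)

  structure(list(
    beta0 = unname(beta0),
    betas = setNames(unname(betas), pred),
    beta_std = beta_std,
    lambda = bundle$lambda,
    scaling = list(center = ctr, scale = scl),
    design = list(predictor_names = pred,
                  penalty_factors = bundle$penalty_factors[pred],
                  standardize = TRUE, intercept = TRUE),
    converged = TRUE,
    n_iter = 0L,
    final_deviance = NA_real_,
    grad_inf = NA_real_,
    fitted = NULL,
    n = bundle$n_train,
    reweighted = TRUE,
    solve_fallback = fallback
  ), class = "ridge_fit")
}

#' @export
print.transfer_bundle <- function(x, ...) {
  cat(sprintf(
    "<transfer_bundle v%s>  %d variables (%d non-droppable), lambda = %.4g, n_train = %d\n",
    x$format_version, length(x$variable_names), length(x$always_keep),
    x$lambda, x$n_train))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
tidy.transfer_bundle <- function(x, ...) {
  tibble(
    variable = x$variable_names,
    v = unname(x$v),
    penalty_factor = unname(x$penalty_factors),
    always_keep = x$variable_names %in% x$always_keep,
    center = unname(x$scaling$center),
    scale = unname(x$scaling$scale)
  )
}

#' @export
glance.transfer_bundle <- function(x, ...) {
  tibble(n_variables = length(x$variable_names), lambda = x$lambda,
         n_train = x$n_train, format_version = x$format_version)
}

#' Save / load a transfer bundle
#'
#' Bundles are written as a versioned JSON container. `M`, `v` and the
#' scaling vectors are base64-encoded IEEE doubles, so the round trip is
#' bit-exact; a byte-sum checksum over the encoded matrices guards against
#' truncation or corruption.
#'
#' @param bundle A `transfer_bundle`.
#' @param path File path (conventionally `.ftm.json`).
#' @return `save_bundle()` returns `path` invisibly; `load_bundle()`
#'   returns the reconstructed `transfer_bundle`.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "transfer_bundle"))
  enc <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8))
  payload <- list(
    format_version = bundle$format_version,
    variable_names = bundle$variable_names,
    n_variables = length(bundle$variable_names),
    lambda = bundle$lambda,
    n_train = bundle$n_train,
    penalty_factors = unname(bundle$penalty_factors),
    always_keep = bundle$always_keep,
    provenance = bundle$provenance,
    M_base64 = enc(bundle$M),
    v_base64 = enc(bundle$v),
    center_base64 = enc(bundle$scaling$center),
    scale_base64 = enc(bundle$scaling$scale),
    checksum = bundle_checksum(bundle)
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  payload <- tryCatch(jsonlite::fromJSON(path),
                      error = function(e) abort(paste0(
                        "Cannot parse transfer bundle file: ", conditionMessage(e))))
  need <- c("format_version", "variable_names", "lambda", "penalty_factors",
            "M_base64", "v_base64", "center_base64", "scale_base64", "checksum")
  miss <- setdiff(need, names(payload))
  if (length(miss) > 0) {
    abort(paste0("Truncated or invalid bundle file; missing fields: ",
                 paste(miss, collapse = ", ")))
  }
  if (!identical(payload$format_version, "1.0")) {
    abort(sprintf("Unsupported bundle format version '%s' (expected 1.0).",
                  payload$format_version))
  }
  dec <- function(s) readBin(jsonlite::base64_dec(s), "numeric",
                             n = 1e8, size = 8)
  vars <- payload$variable_names
  qq <- length(vars)
  Mv <- dec(payload$M_base64)
  if (length(Mv) != qq * qq) abort("Bundle file corrupt: M has the wrong size.")
  bundle <- structure(list(
    variable_names = vars,
    M = matrix(Mv, qq, qq, dimnames = list(vars, vars)),
    v = setNames(dec(payload$v_base64), vars),
    lambda = payload$lambda,
    penalty_factors = setNames(payload$penalty_factors, vars),
    scaling = list(center = setNames(dec(payload$center_base64), vars),
                   scale = setNames(dec(payload$scale_base64), vars)),
    always_keep = payload$always_keep,
    n_train = payload$n_train,
    format_version = payload$format_version,
    provenance = payload$provenance %||% ""
  ), class = "transfer_bundle")
  if (!identical(bundle_checksum(bundle), payload$checksum)) {
    abort("Bundle checksum mismatch: file corrupt or tampered with.")
  }
  bundle
}

bundle_checksum <- function(bundle) {
  raws <- writeBin(as.numeric(c(bundle$M, bundle$v,
                                bundle$scaling$center, bundle$scaling$scale)),
                   raw(), size = 8)
  sum(as.integer(raws)) %% 2147483647L
}
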