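#' Ridge-penalized logistic regression via IRLS
#'
#' Fits P(Y=1|X) = 1 / (1 + exp(-(b0 + X b))) by minimizing the average
#' binomial negative log-likelihood plus a quadratic penalty,
#' \deqn{f(\beta) = \frac{1}{n}\sum_i -\ell_i(\beta) +
#'   \frac{\lambda}{2}\sum_j \phi_j \beta_j^2,}
#' where the penalty factors \eqn{\phi_j} allow adjustment covariates to be
#' left unpenalized (factor 0). Optimization is by iteratively reweighted
#' least squares (IRLS) with step halving; the quadratic penalty enters each
#' weighted least-squares solve. When `standardize = TRUE` (the default, and
#' required for scale-fair shrinkage) predictors are centered and scaled
#' internally and the coefficients are reported back on the input scale.
#'
#' The penalty applies on the standardized scale; averaging the deviance
#' over n makes `lambda` comparable across sample sizes. At convergence the
#' penalized score equation \eqn{X^T(y - p) = n\lambda P \beta} holds on the
#' standardized scale, which is what makes the transfer-matrix
#' reconstruction in [build_transfer_bundle()] an exact identity.
#'
#' @param x Numeric matrix or data frame of predictors (no intercept
#'   column), one row per sample, named columns.
#' @param y Binary outcome vector (0/1 or logical), both classes present.
#' @param lambda Non-negative ridge penalty.
#' @param penalty_factors Per-predictor non-negative penalty multipliers;
#'   0 leaves a predictor unpenalized. Default: 1 for every predictor.
#' @param standardize Center/scale predictors internally (default `TRUE`).
#' @param max_iter Maximum IRLS iterations.
#' @param tol_grad Stop once the infinity norm of the penalized gradient
#'   falls below this value (the fit keeps iterating past the deviance
#'   plateau so the fixed-point identity holds to near machine precision).
#' @param weights Optional non-negative case weights (used internally by
#'   cross-validation; default all 1).
#'
#' @return An object of class `ridge_fit`: intercept and coefficients on
#'   the input scale, standardized-scale coefficients, the scaling used,
#'   penalty metadata and convergence diagnostics.
#' @seealso [cross_validate_lambda()], [predict_proba()],
#'   [build_transfer_bundle()]
#' @export
fit_ridge_logistic <- function(x, y, lambda, penalty_factors = NULL,
                               standardize = TRUE, max_iter = 100L,
                               tol_grad = 1e-11, weights = NULL) {
  x <- as_design_matrix(x)
  y <- check_binary_outcome(y, n = nrow(x))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0) {
    abort("`lambda` must be a single non-negative number.")
  }
  q <- ncol(x)
  if (is.null(penalty_factors)) penalty_factors <- rep(1, q)
  if (length(penalty_factors) != q || any(penalty_factors < 0)) {
    abort("`penalty_factors` must be non-negative, one per predictor.")
  }
  if (nrow(x) < 2L) abort("Need at least two samples.")
  if (!all(is.finite(x))) abort("`x` contains non-finite values.")

  std <- standardize_design(x, standardize)
  Xs <- cbind(`(Intercept)` = 1, std$xs)
  pf <- c(0, penalty_factors)

  res <- irls_ridge(Xs, y, lambda, pf,
                    max_iter = max_iter, tol_grad = tol_grad,
                    weights = weights)
  if (!res$converged) {
    warn(sprintf(
      "IRLS did not reach the gradient tolerance in %d iterations (|grad|_inf = %.3g).",
      res$n_iter, res$grad_inf))
  }

  beta_std <- drop(res$beta)
  names(beta_std) <- colnames(Xs)
  betas <- beta_std[-1] / std$scale
  beta0 <- beta_std[1] - sum(beta_std[-1] * std$center / std$scale)

  structure(list(
    beta0 = unname(beta0),
    betas = setNames(unname(betas), colnames(x)),
    beta_std = beta_std,
    lambda = lambda,
    scaling = list(center = setNames(std$center, colnames(x)),
                   scale = setNames(std$scale, colnames(x))),
    design = list(predictor_names = colnames(x),
                  penalty_factors = setNames(penalty_factors, colnames(x)),
                  standardize = standardize, intercept = TRUE),
    converged = res$grad_inf < 1e-7,
    n_iter = res$n_iter,
    final_deviance = res$deviance,
    grad_inf = res$grad_inf,
    fitted = drop(res$p),
    n = nrow(x),
    reweighted = FALSE
  ), class = "ridge_fit")
}

#' Predicted probabilities from a ridge-logistic fit
#'
#' Columns of `newdata` must match the fit's predictor names exactly and in
#' order; no silent reordering is performed. Probabilities are clipped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' @param fit A `ridge_fit`.
#' @param newdata Matrix or data frame whose columns are exactly
#'   `fit$design$predictor_names`, in order.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(fit, newdata) {
  stopifnot(inherits(fit, "ridge_fit"))
  x <- as_design_matrix(newdata)
  want <- fit$design$predictor_names
  if (!identical(colnames(x), want)) {
    abort(paste0(
      "Column names/order of `newdata` must match the fit exactly.\n",
      "expected: ", paste(head(want, 5), collapse = ", "),
      if (length(want) > 5) ", ..." else "", "\n",
      "got:      ", paste(head(colnames(x), 5), collapse = ", "),
      if (ncol(x) > 5) ", ..." else ""))
  }
  eta <- fit$beta0 + drop(x %*% fit$betas)
  pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf(
    "<ridge_fit>  %d predictors, lambda = %.4g%s\n  deviance = %.4f, %d IRLS iterations, converged: %s\n",
    length(x$betas), x$lambda,
    if (isTRUE(x$reweighted)) " (re-weighted from transfer bundle)" else "",
    x$final_deviance, x$n_iter, x$converged))
  invisible(x)
}

#' @export
tidy.ridge_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", names(x$betas)),
    estimate = c(x$beta0, unname(x$betas)),
    estimate_std = unname(x$beta_std),
    penalty_factor = c(0, unname(x$design$penalty_factors))
  )
}

#' @export
glance.ridge_fit <- function(x, ...) {
  tibble(lambda = x$lambda, deviance = x$final_deviance,
         n_iter = x$n_iter, converged = x$converged,
         nobs = x$n %||% NA_integer_)
}

#' Cross-validated selection of the ridge penalty
#'
#' Ten-fold (by default) cross-validation of the held-out binomial deviance
#' over a descending log-spaced lambda grid, with folds stratified by
#' outcome. The selected `lambda_min` is the smallest lambda attaining the
#' minimum mean held-out deviance (least regularization among exact ties).
#'
#' The default grid has 100 log-spaced values from
#' \eqn{\lambda_{max} = \max_j |x_j^T (y - \bar y)| / (0.001 n)} down to
#' \eqn{10^{-4}\lambda_{max}}, computed over penalized predictors on the
#' standardized scale.
#'
#' @inheritParams fit_ridge_logistic
#' @param n_folds Number of folds (default 10).
#' @param lambda_grid Optional decreasing grid; computed if `NULL`.
#' @param n_lambda Grid length when the grid is computed.
#' @param lambda_min_ratio Ratio of smallest to largest grid value.
#' @param seed Integer seed controlling fold assignment (required for
#'   reproducibility; the caller's RNG stream is left untouched).
#' @return A `cv_ridge` object: `lambda_grid`, `mean_cv_deviance`
#'   (per-observation held-out deviance), `se_cv_deviance`, `lambda_min`,
#'   and `fold_assignments`.
#' @export
cross_validate_lambda <- function(x, y, penalty_factors = NULL,
                                  n_folds = 10L, lambda_grid = NULL,
                                  n_lambda = 100L, lambda_min_ratio = 1e-4,
                                  standardize = TRUE, seed = 1L) {
  x <- as_design_matrix(x)
  y <- check_binary_outcome(y, n = nrow(x))
  n <- nrow(x)
  q <- ncol(x)
  if (is.null(penalty_factors)) penalty_factors <- rep(1, q)
  if (n_folds < 2L) abort("`n_folds` must be at least 2.")
  if (min(table(y)) < n_folds) {
    abort("Each outcome class must have at least `n_folds` members for stratified folds.")
  }

  folds <- with_seed(seed, stratified_folds(y, n_folds))
  if (is.null(lambda_grid)) {
    lambda_grid <- default_lambda_grid(x, y, penalty_factors, standardize,
                                       n_lambda, lambda_min_ratio)
  }
  lambda_grid <- sort(as.numeric(lambda_grid), decreasing = TRUE)

  nl <- length(lambda_grid)
  dev_total <- numeric(nl)              # summed held-out deviance
  dev_fold <- matrix(NA_real_, n_folds, nl)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2L) abort("Degenerate fold: training split has one class.")
    std <- standardize_design(x[tr, , drop = FALSE], standardize)
    Xs <- cbind(1, std$xs)
    B <- ridge_logistic_path(Xs, y[tr], lambda_grid, c(0, penalty_factors))
    xv <- sweep(sweep(x[!tr, , drop = FALSE], 2, std$center), 2, std$scale, "/")
    eta <- cbind(1, xv) %*% B
    p <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    dv <- -2 * colSums(log(p) * y[!tr] + log1p(-p) * (1 - y[!tr]))
    dev_total <- dev_total + dv
    dev_fold[k, ] <- dv / sum(!tr)
  }
  mean_dev <- dev_total / n
  se_dev <- apply(dev_fold, 2, sd) / sqrt(n_folds)
  idx <- which(mean_dev == min(mean_dev))
  lambda_min <- lambda_grid[max(idx)]   # grid descends: max index = smallest lambda

  structure(list(
    lambda_grid = lambda_grid,
    mean_cv_deviance = mean_dev,
    se_cv_deviance = se_dev,
    lambda_min = lambda_min,
    fold_assignments = folds,
    n_folds = n_folds,
    seed = seed
  ), class = "cv_ridge")
}

#' @export
print.cv_ridge <- function(x, ...) {
  cat(sprintf(
    "<cv_ridge>  %d-fold CV over %d lambdas in [%.3g, %.3g]\n  lambda_min = %.4g (mean held-out deviance %.4f)\n",
    x$n_folds, length(x$lambda_grid), min(x$lambda_grid),
    max(x$lambda_grid), x$lambda_min,
    x$mean_cv_deviance[match(x$lambda_min, x$lambda_grid)]))
  invisible(x)
}

#' @export
tidy.cv_ridge <- function(x, ...) {
  tibble(lambda = x$lambda_grid,
         mean_cv_deviance = x$mean_cv_deviance,
         se_cv_deviance = x$se_cv_deviance)
}

#' @export
glance.cv_ridge <- function(x, ...) {
  tibble(lambda_min = x$lambda_min, n_folds = x$n_folds,
         n_lambda = length(x$lambda_grid))
}

#' Cross-validate the penalty, then fit on all samples
#'
#' Convenience wrapper reproducing the standard recipe: 10-fold CV picks
#' the lambda with the lowest held-out deviance, then a final model is
#' fitted to all samples at that lambda.
#'
#' @inheritParams cross_validate_lambda
#' @return List with elements `fit` (a [fit_ridge_logistic()] result at
#'   `lambda_min`) and `cv` (the [cross_validate_lambda()] result).
#' @export
fit_ridge_cv <- function(x, y, penalty_factors = NULL, n_folds = 10L,
                         lambda_grid = NULL, n_lambda = 100L,
                         standardize = TRUE, seed = 1L) {
  cv <- cross_validate_lambda(x, y, penalty_factors, n_folds = n_folds,
                              lambda_grid = lambda_grid, n_lambda = n_lambda,
                              standardize = standardize, seed = seed)
  fit <- fit_ridge_logistic(x, y, lambda = cv$lambda_min,
                            penalty_factors = penalty_factors,
                            standardize = standardize)
  list(fit = fit, cv = cv)
}

# ---- internals -------------------------------------------------------------

as_design_matrix <- function(x) {
  if (is.data.frame(x)) {
    bad <- !vapply(x, is.numeric, logical(1))
    if (any(bad)) {
      abort(paste0("Non-numeric predictor columns: ",
                   paste(names(x)[bad], collapse = ", ")))
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix or data frame.")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}

check_binary_outcome <- function(y, n) {
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!is.numeric(y) || length(y) != n || anyNA(y) || !all(y %in% c(0, 1))) {
    abort("`y` must be a 0/1 vector matching the rows of `x`, no missing values.")
  }
  if (length(unique(y)) < 2L) {
    abort("Outcome has a single class; a logistic model cannot be fitted.")
  }
  as.numeric(y)
}

standardize_design <- function(x, standardize) {
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1  # constant columns pass through
    xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  } else {
    center <- rep(0, ncol(x))
    scale <- rep(1, ncol(x))
    xs <- x
  }
  list(xs = xs, center = center, scale = scale)
}

# penalized average negative log-likelihood (the IRLS objective)
penalized_nll <- function(eta, y, lambda, pf, beta, w = NULL) {
  p <- pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
  ll <- y * log(p) + (1 - y) * log1p(-p)
  if (!is.null(w)) ll <- w * ll
  nobs <- if (is.null(w)) length(y) else sum(w)
  -sum(ll) / nobs + lambda / 2 * sum(pf * beta^2)
}

# IRLS for the penalized objective on a design that already includes the
# intercept column. Returns standardized-scale coefficients.
irls_ridge <- function(Xs, y, lambda, pf, beta_init = NULL,
                       max_iter = 100L, tol_grad = 1e-11, weights = NULL) {
  n <- nrow(Xs)
  qq <- ncol(Xs)
  wts <- weights %||% rep(1, n)
  nobs <- sum(wts)
  beta <- beta_init %||% numeric(qq)
  eta <- drop(Xs %*% beta)
  obj <- penalized_nll(eta, y, lambda, pf, beta, if (is.null(weights)) NULL else wts)
  grad_inf <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
    w <- wts * p * (1 - p)
    grad <- drop(crossprod(Xs, wts * (p - y))) / nobs + lambda * pf * beta
    grad_inf <- max(abs(grad))
    if (grad_inf < tol_grad) { iter <- iter - 1L; break }

    # Newton step: (X'WX/n + lambda P) beta_new = X'W z / n,
    # z = eta + (y - p)/w' with w' = p(1-p) (case weights enter W, not z)
    H <- crossprod(Xs, Xs * w) / nobs
    diag(H) <- diag(H) + lambda * pf
    z <- eta + (y - p) / (p * (1 - p))
    rhs <- drop(crossprod(Xs, w * z)) / nobs
    beta_new <- tryCatch(
      drop(chol2inv_solve(H, rhs)),
      error = function(e) abort(paste0("IRLS weighted least-squares solve failed: ",
                                       conditionMessage(e))))
    # step halving if the penalized objective increased
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      eta_try <- drop(Xs %*% beta_try)
      obj_try <- penalized_nll(eta_try, y, lambda, pf, beta_try,
                               if (is.null(weights)) NULL else wts)
      if (obj_try <= obj + 1e-14 || step < 1e-8) break
      step <- step / 2
    }
    beta <- beta_try
    eta <- eta_try
    obj <- obj_try
    if (iter >= max_iter) break
  }
  p <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  dev <- -2 * sum(wts * (y * log(p) + (1 - y) * log1p(-p)))
  list(beta = beta, p = p, deviance = dev, n_iter = iter,
       grad_inf = grad_inf, converged = grad_inf < tol_grad)
}

# solve H x = b for symmetric positive-definite H via Cholesky
chol2inv_solve <- function(H, b) {
  R <- chol(H)
  backsolve(R, forwardsolve(t(R), b))
}

# warm-started coefficient path over a descending lambda grid; looser
# tolerance than a final fit (used inside cross-validation only)
ridge_logistic_path <- function(Xs, y, lambdas, pf, tol_grad = 1e-7,
                                max_iter = 50L) {
  B <- matrix(0, ncol(Xs), length(lambdas))
  beta <- numeric(ncol(Xs))
  for (i in seq_along(lambdas)) {
    res <- irls_ridge(Xs, y, lambdas[i], pf, beta_init = beta,
                      max_iter = max_iter, tol_grad = tol_grad)
    beta <- res$beta
    B[, i] <- beta
  }
  B
}

default_lambda_grid <- function(x, y, penalty_factors, standardize,
                                n_lambda, lambda_min_ratio) {
  std <- standardize_design(x, standardize)
  n <- nrow(x)
  score <- abs(drop(crossprod(std$xs, y - mean(y))))
  pen <- penalty_factors > 0
  if (!any(pen)) return(10^seq(2, -4, length.out = n_lambda))
  lambda_max <- max(score[pen]) / (n * 0.001)
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = n_lambda))
}

stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}
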