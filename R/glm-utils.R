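#' Ordinary least squares with Wald statistics
#'
#' Standard OLS with per-coefficient standard errors and t-test p-values
#' (n - q degrees of freedom), via [stats::lm()]. Rank deficiency is an
#' explicit error naming the collinear columns rather than a silent drop.
#'
#' @param x Numeric matrix or data frame of predictors (no intercept
#'   column; one is added).
#' @param y Numeric response.
#' @return Tibble with columns `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`.
#' @export
ols_with_stats <- function(x, y) {
  if (is.null(x)) {  # intercept-only model
    n <- length(y)
    se <- sd(y) / sqrt(n)
    tt <- mean(y) / se
    return(tibble(term = "(Intercept)", estimate = mean(y), std_error = se,
                  statistic = tt, p_value = 2 * pt(-abs(tt), n - 1)))
  }
  x <- as_design_matrix(x)
  if (!is.numeric(y) || length(y) != nrow(x)) {
    abort("`y` must be numeric with one value per row of `x`.")
  }
  X <- cbind(`(Intercept)` = 1, x)
  if (nrow(X) <= ncol(X)) abort("Need n > q for OLS with Wald statistics.")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort(paste0("Design matrix is rank deficient; collinear columns: ",
                 paste(dropped, collapse = ", ")))
  }
  df <- as.data.frame(x)
  df$.y <- y
  fit <- lm(.y ~ ., data = df)
  sm <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      # noiseless fixtures legitimately produce zero residual variance
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble(term = c("(Intercept)", colnames(x)),
         estimate = unname(sm[, 1]),
         std_error = unname(sm[, 2]),
         statistic = unname(sm[, 3]),
         p_value = unname(sm[, 4]))
}

#' Unpenalized logistic regression with Wald statistics
#'
#' Maximum-likelihood logistic regression via [stats::glm()] with Wald
#' z-test p-values. Complete or quasi-complete separation is detected
#' (fitted probabilities numerically at 0/1) and reported through the
#' `separation` attribute and a warning; a single-class outcome is an
#' error.
#'
#' @inheritParams ols_with_stats
#' @param y Binary response (0/1).
#' @return Tibble with columns `term`, `estimate` (log odds), `std_error`,
#'   `statistic`, `p_value`; attribute `separation` (logical).
#' @export
logistic_with_stats <- function(x, y) {
  x <- as_design_matrix(x)
  y <- check_binary_outcome(y, n = nrow(x))
  df <- as.data.frame(x)
  df$.y <- y
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!sep) sep <- any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)
  if (sep) warn("Possible separation: fitted probabilities numerically 0 or 1.")
  sm <- summary(fit)$coefficients
  out <- tibble(term = c("(Intercept)", colnames(x)),
                estimate = unname(sm[, 1]),
                std_error = unname(sm[, 2]),
                statistic = unname(sm[, 3]),
                p_value = unname(sm[, 4]))
  attr(out, "separation") <- sep
  out
}
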