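# shared fixture builders; everything is generated in code, seeded

# small logistic-regression dataset with mild signal (never separable at
# these sizes)
make_logistic_data <- function(n, q, seed, beta_scale = 0.6) {
  set.seed(seed)
  x <- matrix(rnorm(n * q), n, q)
  colnames(x) <- paste0("x", seq_len(q))
  beta <- rnorm(q, 0, beta_scale)
  y <- rbinom(n, 1, plogis(0.2 + drop(x %*% beta)))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(x = x, y = y, beta = beta)
}

# independent oracle: minimize the penalized average binomial deviance with
# a general-purpose quasi-Newton optimizer on the standardized design
oracle_ridge_coefs <- function(x, y, lambda, penalty_factors = rep(1, ncol(x))) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  Xs <- cbind(1, sweep(sweep(x, 2, ctr), 2, scl, "/"))
  pf <- c(0, penalty_factors)
  n <- nrow(Xs)
  fn <- function(b) {
    eta <- drop(Xs %*% b)
    -mean(y * eta - log1p(exp(eta))) + lambda / 2 * sum(pf * b^2)
  }
  gr <- function(b) {
    p <- plogis(drop(Xs %*% b))
    drop(crossprod(Xs, p - y)) / n + lambda * pf * b
  }
  o <- stats::optim(numeric(ncol(Xs)), fn, gr, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-16))
  b <- o$par
  betas <- b[-1] / scl
  c(b[1] - sum(b[-1] * ctr / scl), betas)  # original-scale (b0, betas)
}

# brute-force pairwise AUC with half credit for ties
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (s in pos) total <- total + sum(s > neg) + 0.5 * sum(s == neg)
  total / (length(pos) * length(neg))
}

# brute-force Benjamini-Hochberg step-up
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * ps[i:m] / (i:m))
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# small cohort fixture for pipeline-level tests
small_sim <- function(n = 400, n_classes = 4, species = 8, seed = 11, ...) {
  simulate_cohort(sim_config(n_samples = n, n_classes = n_classes,
                             species_per_class = species, seed = seed, ...))
}
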