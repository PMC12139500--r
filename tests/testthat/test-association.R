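test_that("noiseless paired data recover statin effects exactly, interactions zero", {
  sim <- small_sim(n = 500, seed = 7, statin_prevalence_target = 0.4)
  n <- nrow(sim$cohort)
  statin <- rep(c(0L, 1L), length.out = n)
  fu <- simulate_followup(sim$cohort, sim$truth, noise_sd = 0, seed = 2,
                          statin = statin)
  res <- statin_effect_scan(sim$cohort, fu)
  main <- res[res$term == "statin", ]
  inter <- res[res$term == "statin:baseline", ]
  expect_equal(setNames(main$beta, main$lipid), sim$truth$statin_deltas,
               tolerance = 1e-8)
  expect_lt(max(abs(inter$beta)), 1e-8)
  expect_equal(main$model_tag[1], "baseline_adjusted")
})

test_that("a null statin effect is calibrated: ~5% raw, ~0 corrected", {
  frac_p <- c(); frac_q <- c()
  for (s in 1:10) {
    sim <- simulate_cohort(sim_config(n_samples = 400, n_classes = 25,
                                      species_per_class = 10,
                                      within_class_corr = 0,
                                      statin_effect_scale = 0,
                                      statin_prevalence_target = 0.4, seed = s))
    statin <- rep(c(0L, 1L), 200)
    fu <- simulate_followup(sim$cohort, sim$truth, noise_sd = 0.3,
                            seed = s + 100, statin = statin)
    res <- statin_effect_scan(sim$cohort, fu)
    main <- res[res$term == "statin", ]
    frac_p <- c(frac_p, mean(main$p < 0.05))
    frac_q <- c(frac_q, mean(main$q < 0.05))
  }
  expect_lt(abs(mean(frac_p) - 0.05), 0.02)
  expect_lte(mean(frac_q), 0.05)
})

test_that("strong effects are detected with the right sign", {
  sim <- simulate_cohort(sim_config(n_samples = 3000, n_classes = 10,
                                    species_per_class = 10,
                                    statin_effect_frac_negative = 0.8,
                                    statin_effect_scale = 0.3, seed = 83))
  noise_sd <- 0.2
  statin <- rep(c(0L, 1L), 1500)
  fu <- simulate_followup(sim$cohort, sim$truth, noise_sd = noise_sd,
                          seed = 84, statin = statin)
  res <- statin_effect_scan(sim$cohort, fu)
  main <- res[res$term == "statin", ]
  deltas <- sim$truth$statin_deltas[main$lipid]
  strong <- abs(deltas) > 2 * noise_sd
  expect_gte(mean(sign(main$beta[strong]) == sign(deltas[strong])), 0.95)
})

test_that("the 12-month clinical-lipid variant swaps the adjustment set", {
  sim <- small_sim(n = 300, seed = 29)
  fu <- simulate_followup(sim$cohort, sim$truth, noise_sd = 0.2, seed = 3)
  res <- statin_effect_scan(sim$cohort, fu, adjust_followup_clinical = TRUE)
  expect_equal(unique(res$model_tag), "clinical12m_adjusted")
  expect_true(all(c("statin", "statin:baseline") %in% res$term))
})

test_that("unpaired inputs are rejected", {
  sim <- small_sim(n = 100, seed = 37)
  fu <- simulate_followup(sim$cohort, sim$truth, noise_sd = 0.1, seed = 4)
  fu$sample_id <- paste0("other_", fu$sample_id)
  expect_error(statin_effect_scan(sim$cohort, fu), "No paired samples")
})

test_that("CVD scan: a null lipid shows matching adjusted/unadjusted estimates", {
  diffs <- vapply(1:25, function(s) {
    sim <- simulate_cohort(sim_config(n_samples = 1200, n_classes = 1,
                                      species_per_class = 5,
                                      n_cvd_causal_lipids = 0,
                                      statin_effect_scale = 0,
                                      cvd_prevalence_target = 0.2,
                                      statin_prevalence_target = 0.3, seed = s))
    lc <- log_transform(sim$cohort)
    un <- cvd_assoc_scan(lc, adjust_statin = FALSE)
    ad <- cvd_assoc_scan(lc, adjust_statin = TRUE)
    un$beta[1] - ad$beta[1]
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.02)
})

test_that("statin adjustment attenuates confounded lipid-CVD associations", {
  hits <- vapply(1:30, function(s) {
    sim <- simulate_cohort(sim_config(
      n_samples = 1500, n_classes = 1, species_per_class = 6,
      statin_prevalence_target = 0.3, statin_effect_scale = 0.8,
      statin_effect_frac_negative = 1, n_cvd_causal_lipids = 0,
      cvd_statin_beta = 1.2, cvd_prevalence_target = 0.15, seed = 400 + s))
    lc <- log_transform(sim$cohort)
    target <- names(which.min(sim$truth$statin_deltas))
    un <- cvd_assoc_scan(lc, adjust_statin = FALSE)
    ad <- cvd_assoc_scan(lc, adjust_statin = TRUE)
    abs(un$beta[un$lipid == target]) > abs(ad$beta[ad$lipid == target])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("binary lipid surrogate log OR matches the 2x2 table", {
  set.seed(91)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1 + 1.5 * x))
  res <- suppressWarnings(
    logistic_with_stats(matrix(x, ncol = 1, dimnames = list(NULL, "lip")), y))
  tab <- table(x, y)
  expect_equal(res$estimate[2],
               log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])),
               tolerance = 1e-8)
})

test_that("BH q-values match brute-force step-up and are monotone in p", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               brute_force_bh(c(0.01, 0.02, 0.03, 0.5)))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(6)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_force_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("orthogonal covariates leave OLS lipid effects unchanged", {
  set.seed(14)
  n <- 200
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x + y))   # orthogonal to both by construction
  b1 <- ols_with_stats(cbind(x = x), y)$estimate[2]
  b2 <- ols_with_stats(cbind(x = x, z = z), y)$estimate[2]
  expect_lt(abs(b1 - b2), 1e-6)
})

test_that("classification and crosstab bookkeeping is exact", {
  mk <- function(p, q) tibble::tibble(lipid = paste0("L", seq_along(p)), p = p, q = q)
  un <- mk(p = c(0.001, 0.01, 0.2, 0.03, 0.6, 0.002),
           q = c(0.004, 0.06, 0.4, 0.09, 0.8, 0.01))
  ad <- mk(p = c(0.001, 0.3, 0.02, 0.5, 0.7, 0.004),
           q = c(0.01, 0.5, 0.07, 0.7, 0.9, 0.3))
  res <- classify_and_crosstab(un, ad)
  # expected classes -- unadjusted: corr, nominal, none, nominal, none, corr
  #                     adjusted:   corr, none, nominal, none, none, nominal
  lv <- c("corrected_p_lt_0.05", "p_lt_0.05", "p_ge_0.05")
  expected <- matrix(0L, 3, 3, dimnames = list(unadjusted = lv, adjusted = lv))
  expected["corrected_p_lt_0.05", "corrected_p_lt_0.05"] <- 1L
  expected["corrected_p_lt_0.05", "p_lt_0.05"] <- 1L
  expected["p_lt_0.05", "p_ge_0.05"] <- 2L
  expected["p_ge_0.05", "p_lt_0.05"] <- 1L
  expected["p_ge_0.05", "p_ge_0.05"] <- 1L
  expect_equal(unclass(res$crosstab), unclass(expected))
  expect_equal(res$n_consistent + res$n_changed, 6)
  expect_equal(sum(res$crosstab), 6)

  # identical tables sit on the diagonal
  res_id <- classify_and_crosstab(un, un)
  expect_equal(res_id$n_changed, 0)
  expect_equal(res_id$n_consistent, 6)

  expect_error(classify_and_crosstab(un, ad[-1, ]), "same lipid set")
})
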