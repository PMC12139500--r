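test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_samples = 150, n_classes = 3, species_per_class = 5,
                    seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth, s2$truth)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(within_class_corr = 1), "positive-definite")
  expect_error(sim_config(within_class_corr = -0.1), "positive-definite")
  expect_error(sim_config(statin_prevalence_target = 0), "prevalence")
  expect_error(sim_config(n_samples = 0), "n_samples")
  expect_error(sim_config(statin_effect_frac_negative = 1.2), "frac_negative")
})

test_that("zero statin effect yields null two-sample t-tests at the nominal rate", {
  sim <- simulate_cohort(sim_config(n_samples = 600, n_classes = 30,
                                    species_per_class = 10,
                                    within_class_corr = 0,
                                    statin_effect_scale = 0,
                                    statin_prevalence_target = 0.3,
                                    seed = 17))
  m <- log(lipid_matrix(sim$cohort))
  g <- sim$cohort$statin
  pvals <- apply(m, 2, function(v) stats::t.test(v[g == 1], v[g == 0])$p.value)
  rej <- mean(pvals < 0.05)
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.10)
  expect_true(all(abs(sim$truth$statin_deltas) == 0))
})

test_that("within-class correlation matches the specified covariance", {
  sim <- simulate_cohort(sim_config(n_samples = 5000, n_classes = 3,
                                    species_per_class = 10,
                                    within_class_corr = 0.8,
                                    statin_effect_scale = 0, seed = 23))
  m <- log(lipid_matrix(sim$cohort))
  cors <- stats::cor(m)
  within <- c()
  between <- c()
  cls <- rep(1:3, each = 10)
  for (i in 1:29) for (j in (i + 1):30) {
    if (cls[i] == cls[j]) within <- c(within, cors[i, j])
    else between <- c(between, cors[i, j])
  }
  expect_gt(mean(within), 0.75)
  expect_lt(mean(within), 0.85)
  expect_lt(abs(mean(between)), 0.02)
})

test_that("realized statin prevalence tracks the target across seeds", {
  target <- 0.084
  prev <- vapply(1:30, function(s) {
    mean(simulate_cohort(sim_config(n_samples = 2000, n_classes = 2,
                                    species_per_class = 5,
                                    statin_prevalence_target = target,
                                    seed = s))$cohort$statin)
  }, numeric(1))
  expect_lt(abs(mean(prev) - target) / target, 0.05)
  expect_gte(mean(abs(prev - target) / target <= 0.2), 0.9)
})

test_that("all generated concentrations are strictly positive", {
  sim <- small_sim(seed = 31)
  expect_true(all(lipid_matrix(sim$cohort) > 0))
  fu <- simulate_followup(sim$cohort, sim$truth, noise_sd = 0.3, seed = 5)
  expect_true(all(lipid_matrix(fu) > 0))
})

test_that("noiseless follow-up reproduces baseline and exact statin shifts", {
  sim <- small_sim(seed = 41)
  n <- nrow(sim$cohort)
  fu0 <- simulate_followup(sim$cohort, sim$truth, noise_sd = 0, seed = 1,
                           statin = rep(0, n))
  expect_equal(lipid_matrix(fu0), lipid_matrix(sim$cohort), tolerance = 1e-12)

  fu1 <- simulate_followup(sim$cohort, sim$truth, noise_sd = 0, seed = 1,
                           statin = rep(1, n))
  diff <- log(lipid_matrix(fu1)) - log(lipid_matrix(sim$cohort))
  expect_equal(colMeans(diff), sim$truth$statin_deltas, tolerance = 1e-10)
  expect_lt(max(apply(diff, 2, sd)), 1e-10)
})

test_that("per-lipid regression on follow-up recovers the statin effects", {
  sim <- simulate_cohort(sim_config(n_samples = 4000, n_classes = 2,
                                    species_per_class = 10, seed = 57))
  noise_sd <- 0.3
  statin <- rep(c(0L, 1L), 2000)
  fu <- simulate_followup(sim$cohort, sim$truth, noise_sd = noise_sd,
                          seed = 8, statin = statin)
  lb <- log(lipid_matrix(sim$cohort))
  lf <- log(lipid_matrix(fu))
  est <- vapply(colnames(lb), function(l) {
    coef(lm(lf[, l] ~ statin + lb[, l]))[["statin"]]
  }, numeric(1))
  mae <- mean(abs(est - sim$truth$statin_deltas))
  expect_lt(mae, 3 * noise_sd / sqrt(4000))
})

test_that("QC replicates have the right medians and degenerate behavior", {
  ref <- setNames(runif(50, 0.1, 20), paste0("L", 1:50))
  sf <- setNames(runif(50, 0.5, 2), paste0("L", 1:50))
  # cv -> 0: replicates equal reference x scale exactly
  qc0 <- simulate_qc_replicates(ref, sf, n_reps = 3, cv = 0, seed = 2)
  expect_equal(qc0[1, ], ref * sf, tolerance = 1e-12)
  expect_equal(qc0[3, ], ref * sf, tolerance = 1e-12)

  qc <- simulate_qc_replicates(ref, rep(1, 50), n_reps = 1000, cv = 0.1, seed = 3)
  med <- apply(qc, 2, median)
  expect_true(all(abs(med / ref - 1) < 0.02))

  one <- simulate_qc_replicates(ref, sf, n_reps = 1, cv = 0.2, seed = 4)
  expect_equal(dim(one), c(1L, 50L))
  expect_true(all(one > 0))

  expect_error(simulate_qc_replicates(ref, sf[-1], 2, 0.1), "same length")
  expect_error(simulate_qc_replicates(-ref, sf, 2, 0.1), "positive")
})

test_that("the negative-effect fraction is honored exactly", {
  sim <- simulate_cohort(sim_config(n_samples = 50, n_classes = 4,
                                    species_per_class = 25,
                                    statin_effect_frac_negative = 0.9,
                                    seed = 71))
  expect_equal(sum(sim$truth$statin_deltas < 0), round(0.9 * 100))
})
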