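make_panel <- function(p = 20, seed = 5) {
  set.seed(seed)
  reference_panel(paste0("L", seq_len(p)), runif(p, 0.05, 30))
}

test_that("QC factors are the reference / median ratio, with scale equivariance", {
  panel <- make_panel()
  ref <- setNames(panel$concentration, panel$lipid)
  qc <- simulate_qc_replicates(ref, rep(1, 20), n_reps = 5, cv = 0, seed = 1)
  f <- qc_correction_factors(panel, qc)
  expect_equal(f$factor, rep(1, 20), tolerance = 1e-12)

  f2 <- qc_correction_factors(panel, qc * 2)
  expect_equal(f2$factor, rep(0.5, 20), tolerance = 1e-12)

  # equivariance: scaling QC by c divides factors by c
  f3 <- qc_correction_factors(panel, qc * 3)
  expect_equal(f3$factor, f$factor / 3, tolerance = 1e-12)
})

test_that("noisy QC recovers the true inverse scale within 3% for most lipids", {
  set.seed(9)
  p <- 100
  panel <- reference_panel(paste0("L", 1:p), runif(p, 0.1, 25))
  ref <- setNames(panel$concentration, panel$lipid)
  true_scale <- setNames(runif(p, 0.4, 2.5), panel$lipid)
  qc <- simulate_qc_replicates(ref, true_scale, n_reps = 100, cv = 0.1, seed = 10)
  f <- qc_correction_factors(panel, qc)
  rel_err <- abs(f$factor * true_scale[f$lipid] - 1)
  expect_gte(mean(rel_err < 0.03), 0.95)
})

test_that("QC lipids absent from the panel are flagged, empty overlap fatal", {
  panel <- make_panel()
  ref <- setNames(panel$concentration, panel$lipid)
  qc <- simulate_qc_replicates(ref, rep(1, 20), n_reps = 3, cv = 0.05, seed = 2)
  colnames(qc)[1] <- "not_in_panel"
  expect_message(f <- qc_correction_factors(panel, qc), "absent from the reference panel")
  expect_equal(attr(f, "unmatched_lipids"), "not_in_panel")
  expect_equal(nrow(f), 19)

  colnames(qc) <- paste0("other", seq_len(ncol(qc)))
  expect_error(qc_correction_factors(panel, qc), "No lipid overlap")
})

test_that("applying factors and their inverses round-trips the cohort", {
  sim <- small_sim(seed = 3)
  lipids <- lipid_names(sim$cohort)
  set.seed(1)
  fac <- structure(tibble::tibble(lipid = lipids,
                                  factor = runif(length(lipids), 0.5, 2),
                                  method = "qc_ratio", n_used = 1L),
                   class = c("correction_factors", class(tibble::tibble())))
  corrected <- apply_factors(sim$cohort, fac)
  inv <- fac
  inv$factor <- 1 / fac$factor
  back <- apply_factors(corrected, inv)
  expect_equal(lipid_matrix(back), lipid_matrix(sim$cohort), tolerance = 1e-12)

  # identity factors change nothing
  idf <- fac; idf$factor <- rep(1, nrow(fac))
  expect_equal(lipid_matrix(apply_factors(sim$cohort, idf)),
               lipid_matrix(sim$cohort))
})

test_that("harmonization is idempotent: corrected QC medians sit on the panel", {
  panel <- make_panel()
  ref <- setNames(panel$concentration, panel$lipid)
  qc <- simulate_qc_replicates(ref, runif(20, 0.5, 2), n_reps = 7, cv = 0, seed = 6)
  f <- qc_correction_factors(panel, qc)
  qc_corr <- sweep(qc, 2, setNames(f$factor, f$lipid)[colnames(qc)], "*")
  expect_equal(apply(qc_corr, 2, median), ref, tolerance = 1e-12)
  f2 <- qc_correction_factors(panel, qc_corr)
  expect_equal(f2$factor, rep(1, 20), tolerance = 1e-12)
})

test_that("matched sub-cohorts recover per-lipid scale shifts", {
  sim <- small_sim(n = 600, seed = 13)
  target <- sim$cohort
  # exact-copy target: factors are 1 regardless of matching
  f_id <- matched_subcohort_factors(sim$cohort, target,
                                    c("age", "sex", "bmi"), n_pairs = 600)
  expect_equal(f_id$factor, rep(1, length(f_id$factor)), tolerance = 1e-12)

  # scale one lipid by c: factor = 1/c when matching is exact
  l1 <- lipid_names(target)[1]
  target2 <- target
  target2[[l1]] <- target2[[l1]] * 4
  f_sc <- matched_subcohort_factors(sim$cohort, target2,
                                    c("age", "sex", "bmi"), n_pairs = 600)
  expect_equal(f_sc$factor[f_sc$lipid == l1], 0.25, tolerance = 1e-12)
  expect_equal(f_sc$factor[f_sc$lipid != l1], rep(1, nrow(f_sc) - 1),
               tolerance = 1e-12)
})

test_that("matching tolerates covariate shift and recovers known factors", {
  # one generated population split in two, so the species-level concentration
  # distributions agree; the target half is then re-scaled per lipid
  sim <- simulate_cohort(sim_config(n_samples = 2400, n_classes = 5,
                                    species_per_class = 10, seed = 61))
  lipids <- lipid_names(sim$cohort)
  simA <- list(cohort = as_lipid_cohort(sim$cohort[1:1200, ], lipids))
  tgt <- as_lipid_cohort(sim$cohort[1201:2400, ], lipids)
  set.seed(63)
  true_fac <- setNames(runif(50, 0.5, 2), lipid_names(tgt))
  for (l in names(true_fac)) tgt[[l]] <- tgt[[l]] / true_fac[[l]]
  tgt$age <- tgt$age + 5       # shifted covariate distribution
  tgt$bmi <- tgt$bmi * 1.1
  f <- matched_subcohort_factors(simA$cohort, tgt, c("age", "sex", "bmi"),
                                 n_pairs = 500, seed = 64)
  rel_err <- abs(f$factor / true_fac[f$lipid] - 1)
  expect_gte(mean(rel_err < 0.10), 0.90)

  # matched pairs are closer in covariate space than random pairs
  pairs <- attr(f, "matched_pairs")
  expect_lt(mean(pairs$distance), 1)
})

test_that("log transform handles zeros per policy and rejects negatives", {
  sim <- small_sim(n = 50, seed = 19)
  lg <- log_transform(sim$cohort)
  expect_true(attr(lg, "log_scale"))
  expect_equal(lipid_matrix(lg), log(lipid_matrix(sim$cohort)))

  l1 <- lipid_names(sim$cohort)[1]
  withz <- sim$cohort
  withz[[l1]][3] <- 0
  expect_error(log_transform(withz, zero_policy = "error"), "Zero concentration")
  expect_message(lz <- log_transform(withz), "half the minimum")
  expect_equal(lipid_matrix(lz)[3, l1],
               log(min(withz[[l1]][withz[[l1]] > 0]) / 2))

  neg <- sim$cohort
  neg[[l1]][2] <- -1
  expect_error(log_transform(neg), "Negative concentration")

  # double log transform is refused
  expect_error(log_transform(lg), "log-transformed|raw")
})
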