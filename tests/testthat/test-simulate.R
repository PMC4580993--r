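# Synthetic multi-cohort generator: emission contracts, thinning,
# reproducibility, and the per-cohort randomness streams.

test_that("degenerate noise-free normal emission gives the deterministic count", {
  # sigma2 = 0, tau2 = 0, detection = 1, mu = 38, beta = 0.1, ages pinned
  # near 30 -> every count rounds to 38 + 3 = 41
  sp <- cohort_spec("A", c("3" = 5), age_mean = 30, age_sd = 0.01,
                    age_min = 29.9, age_max = 34)
  pp <- generative_params("normal", beta_age = 0.1, mu_cf = 38,
                          sigma2_cf = 0, tau2 = 0)
  sim <- simulate_cohorts(sp, pp, seed = 1)
  expect_true(all(sim$meioses$n_crossovers == 41L))
  expect_true(all(sim$truth$true_counts$true_count == 41L))
})

test_that("negative-binomial emission honours the mean/variance contract", {
  # beta = 0, alpha fixed at log(38) (sigma2 = 0): mean 38, var/mean = omega
  omega <- 1.9
  sp <- cohort_spec("A", c("3" = 5000), age_mean = 28)
  pp <- generative_params("negative_binomial", beta_age = 0, mu_cf = log(38),
                          sigma2_cf = 0, omega = omega)
  y <- simulate_cohorts(sp, pp, seed = 2)$meioses$n_crossovers
  n <- length(y)
  expect_gte(n, 10000)
  se_mean <- sd(y) / sqrt(n)
  expect_lt(abs(mean(y) - 38), 3 * se_mean)
  ratio <- var(y) / mean(y)
  # resampling SE of the variance/mean ratio
  set.seed(99)
  boot <- replicate(200, { i <- sample(n, replace = TRUE); var(y[i]) / mean(y[i]) })
  expect_lt(abs(ratio - omega), 3 * sd(boot))
})

test_that("omega = 1 falls back to Poisson emission", {
  sp <- cohort_spec("A", c("3" = 3000), age_mean = 28)
  pp <- generative_params("negative_binomial", beta_age = 0, mu_cf = log(38),
                          sigma2_cf = 0, omega = 1)
  y <- simulate_cohorts(sp, pp, seed = 3)$meioses$n_crossovers
  ratio <- var(y) / mean(y)
  set.seed(98)
  boot <- replicate(200, { i <- sample(length(y), replace = TRUE); var(y[i]) / mean(y[i]) })
  expect_lt(abs(ratio - 1), 3 * sd(boot))
})

test_that("binomial detection thinning halves the observed mean", {
  # true counts all 40 (noise-free normal), detection 0.5 on configuration 4
  det <- data.frame(cohort = "A", configuration = 1:6,
                    value = c(1, 1, 1, 0.5, 1, 1))
  sp <- cohort_spec("A", c("4" = 5000), age_mean = 30, age_sd = 0.01,
                    age_min = 29.5, age_max = 33)
  pp <- generative_params("normal", beta_age = 0, mu_cf = 40, sigma2_cf = 0,
                          tau2 = 0, detection_prob_cf = det)
  sim <- simulate_cohorts(sp, pp, seed = 4)
  y <- sim$meioses$n_crossovers
  expect_true(all(sim$truth$true_counts$true_count == 40L))
  expect_lt(abs(mean(y) - 20), 3 * sd(y) / sqrt(length(y)))
  # thinning never exceeds the true count
  expect_true(all(y <= 40L))
})

test_that("observed counts equal true counts when detection is 1", {
  sp <- cohort_spec("A", c("2" = 30, "4" = 30))
  pp <- generative_params("negative_binomial", beta_age = 0.002,
                          mu_cf = log(38), sigma2_cf = 0.005, omega = 1.9,
                          detection_prob_cf = 1)
  sim <- simulate_cohorts(sp, pp, seed = 5)
  key <- paste(sim$meioses$parent_id, sim$meioses$child_id)
  tkey <- paste(sim$truth$true_counts$parent_id, sim$truth$true_counts$child_id)
  expect_identical(sim$meioses$n_crossovers,
                   sim$truth$true_counts$true_count[match(key, tkey)])
})

test_that("identical seeds reproduce the tables exactly and ages increase with birth order", {
  specs <- default_cohort_specs(scale = 0.05)
  params <- default_generative_params(specs)
  s1 <- simulate_cohorts(specs, params, seed = 7)
  s2 <- simulate_cohorts(specs, params, seed = 7)
  expect_identical(s1, s2)
  s3 <- simulate_cohorts(specs, params, seed = 8)
  expect_false(identical(s1$meioses$n_crossovers, s3$meioses$n_crossovers))
  # strict age monotonicity within each family
  by_fam <- split(s1$meioses$parent_age_years, s1$meioses$family_id)
  expect_true(all(vapply(by_fam, function(a) all(diff(a) >= 1), logical(1))))
})

test_that("adding a cohort does not perturb the data simulated for the others", {
  specs <- default_cohort_specs(scale = 0.05)
  params <- default_generative_params(specs)
  s_all <- simulate_cohorts(specs, params, seed = 7)
  s_sub <- simulate_cohorts(specs[1:4], params, seed = 7)
  keep <- vapply(specs[1:4], function(s) s$cohort_id, character(1))
  expect_identical(s_sub$meioses,
                   {
                     m <- s_all$meioses[s_all$meioses$cohort %in% keep, ]
                     rownames(m) <- NULL
                     m
                   })
})

test_that("generator rejects invalid parameters", {
  expect_error(generative_params("normal", sigma2_cf = -1), "sigma2")
  expect_error(generative_params("negative_binomial", omega = 0.5), "omega")
  expect_error(generative_params("normal", detection_prob_cf = 0), "detection")
  expect_error(generative_params("negative_binomial",
                                 detection_prob_cf = data.frame(
                                   cohort = "A", configuration = 2, value = 0.8)),
               "fully informative")
  expect_error(cohort_spec("A", c("7" = 3)), "configuration")
  expect_error(cohort_spec("A", age_sd = 0), "age_sd")
})

test_that("call-table expansion matches counts and records injected artifacts", {
  specs <- list(cohort_spec("A", c("2" = 40, "4" = 40), snps_per_mb = 120))
  params <- generative_params("negative_binomial", beta_age = 0,
                              mu_cf = log(38), sigma2_cf = 0.005, omega = 1.9)
  sim <- simulate_cohorts(specs, params, seed = 11)
  # no artifacts: high-confidence calls match the counts exactly
  ct0 <- simulate_call_table(sim$meioses, sim$truth, artifact_rate = 0, seed = 1)
  expect_null(attr(ct0, "injected"))
  expect_identical(nrow(ct0[ct0$posterior_prob > 0.5, ]),
                   as.integer(sum(sim$meioses$n_crossovers)))
  counts0 <- calls_to_counts(threshold_calls(ct0), sim$meioses)
  expect_identical(counts0$n_crossovers, sim$meioses$n_crossovers)

  # low-confidence injections only: the threshold alone restores the counts
  ctl <- simulate_call_table(sim$meioses, sim$truth, artifact_rate = 0,
                             low_conf_rate = 0.5, seed = 2)
  inj <- attr(ctl, "injected")
  expect_true(all(inj$type == "low_prob"))
  countsl <- calls_to_counts(threshold_calls(ctl), sim$meioses)
  expect_identical(countsl$n_crossovers, sim$meioses$n_crossovers)

  # tight-pair injections: the double-crossover filter restores the counts
  ctp <- simulate_call_table(sim$meioses, sim$truth, artifact_rate = 0.2, seed = 3)
  expect_true(all(attr(ctp, "injected")$type == "tight_pair"))
  filt <- filter_double_crossovers(threshold_calls(ctp), sim$truth$snps_per_mb)
  countsp <- calls_to_counts(filt$calls, sim$meioses)
  expect_gte(mean(countsp$n_crossovers == sim$meioses$n_crossovers), 0.99)

  # truth mismatch is rejected
  bad <- sim$meioses
  bad$cohort <- "Z"
  expect_error(simulate_call_table(bad, sim$truth, seed = 1), "match")
})
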