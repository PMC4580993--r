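# MCMC fits of the hierarchical models: closed-form and grid oracles,
# prior-only sanity, convergence bookkeeping, and cross-model agreement.

conjugate_priors <- function() {
  structure(list(beta_mean = 0, beta_sd = 1, mu_mean = 41, mu_var = 100,
                 sigma2_shape = 3, sigma2_scale = 8,
                 tau2_shape = 3, tau2_scale = 18,
                 beta_global_mean = 0, beta_global_sd = 1,
                 sigma2_beta_shape = 3, sigma2_beta_scale = 0.02),
            class = "prior_set")
}

test_that("the conjugate toy posterior matches the closed form", {
  set.seed(3)
  J <- 30
  m <- make_meioses("A", rep(sprintf("P%02d", 1:J), each = 2),
                    sprintf("c%03d", 1:(2 * J)),
                    age = rep(c(25, 28), J), count = rpois(2 * J, 38))
  sigma2 <- 4; tau2 <- 9
  fit <- fit_model(m, model_spec("M1"), priors = conjugate_priors(),
                   mcmc = mcmc_control(n_chains = 4, n_draws = 4000, seed = 11,
                                       n_adapt = 300),
                   fixed = list(beta_age = 0, sigma2 = sigma2, tau2 = tau2),
                   subset = FALSE)
  # marginally, ybar_j ~ N(mu, sigma2 + tau2/2): normal-normal posterior
  ybarj <- tapply(m$n_crossovers, m$parent_id, mean)
  prec <- 1 / 100 + J / (sigma2 + tau2 / 2)
  post_mean <- (41 / 100 + sum(ybarj) / (sigma2 + tau2 / 2)) / prec
  post_sd <- sqrt(1 / prec)
  d <- pooled_draws(fit, "mu[A]")
  mcse <- sd(d) / sqrt(coda::effectiveSize(fit$samples[, "mu[A]"]))
  expect_lt(abs(mean(d) - post_mean), 3 * mcse)
  expect_equal(sd(d), post_sd, tolerance = 0.1)
  expect_lt(max(fit$rhat), 1.05)
})

test_that("with no data the posterior equals the prior", {
  m <- data.frame(cohort = character(0), family_id = character(0),
                  parent_id = character(0), child_id = character(0),
                  parent_sex = character(0), parent_age_years = numeric(0),
                  configuration = integer(0), n_crossovers = integer(0),
                  stringsAsFactors = FALSE)
  fit <- fit_model(m, model_spec("M1"), priors = conjugate_priors(),
                   mcmc = mcmc_control(n_chains = 2, n_draws = 4000, seed = 5,
                                       n_adapt = 100),
                   subset = FALSE)
  d <- pooled_draws(fit, "beta_age")
  mcse <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 4 * mcse)
  expect_equal(sd(d), 1, tolerance = 0.05)
  expect_equal(unname(quantile(d, 0.975)), qnorm(0.975), tolerance = 0.1)
})

test_that("the Poisson-limit toy posterior matches a grid-evaluated oracle", {
  # one mother, two children; mu, sigma2 fixed, omega = 1 (Poisson limit):
  # free parameters are beta and alpha, whose exact posterior is computed
  # on a fine grid
  m <- make_meioses("A", c("P1", "P1"), c("c1", "c2"),
                    age = c(24, 32), count = c(35L, 44L))
  mu0 <- log(38); s2 <- 0.01
  fit <- fit_model(m, model_spec("M2"), priors = conjugate_priors(),
                   mcmc = mcmc_control(n_chains = 4, n_draws = 4000, seed = 7,
                                       n_adapt = 300),
                   fixed = list(mu = mu0, sigma2 = s2, omega = 1),
                   subset = FALSE)
  beta_grid <- seq(-0.3, 0.3, length.out = 401)
  alpha_grid <- seq(mu0 - 0.6, mu0 + 0.6, length.out = 401)
  lp <- outer(beta_grid, alpha_grid, function(b, a) {
    dpois(35, exp(b * 24 + a), log = TRUE) +
      dpois(44, exp(b * 32 + a), log = TRUE) +
      dnorm(a, mu0, sqrt(s2), log = TRUE) + dnorm(b, 0, 1, log = TRUE)
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  exact_beta <- sum(rowSums(w) * beta_grid)
  exact_alpha <- sum(colSums(w) * alpha_grid)
  db <- pooled_draws(fit, "beta_age")
  da <- pooled_draws(fit, "alpha[P1]")
  mcse_b <- sd(db) / sqrt(coda::effectiveSize(fit$samples[, "beta_age"]))
  expect_lt(abs(mean(db) - exact_beta), 4 * mcse_b)
  expect_lt(abs(mean(da) - exact_alpha), 0.02)
  exact_sd_beta <- sqrt(sum(rowSums(w) * beta_grid^2) - exact_beta^2)
  expect_equal(sd(db), exact_sd_beta, tolerance = 0.1)
})

test_that("same seed reproduces the fit; row order does not change the posterior", {
  specs <- list(cohort_spec("C1", c("2" = 30)), cohort_spec("C2", c("2" = 30)))
  sim <- simulate_cohorts(specs, default_generative_params(specs), seed = 13)
  f1 <- fit_model(sim$meioses, model_spec("M2"), mcmc = fast_mcmc(seed = 2),
                  monitor_alpha = FALSE)
  f2 <- fit_model(sim$meioses, model_spec("M2"), mcmc = fast_mcmc(seed = 2),
                  monitor_alpha = FALSE)
  expect_identical(as.matrix(f1$samples[[1]]), as.matrix(f2$samples[[1]]))
  # permuted rows: same posterior up to Monte-Carlo error
  perm <- sim$meioses[rev(seq_len(nrow(sim$meioses))), ]
  f3 <- fit_model(perm, model_spec("M2"), mcmc = fast_mcmc(seed = 2),
                  monitor_alpha = FALSE)
  d1 <- pooled_draws(f1, "beta_age"); d3 <- pooled_draws(f3, "beta_age")
  mcse <- sqrt(sd(d1)^2 / coda::effectiveSize(f1$samples[, "beta_age"]) +
                 sd(d3)^2 / coda::effectiveSize(f3$samples[, "beta_age"]))
  expect_lt(abs(median(d1) - median(d3)), 5 * mcse)
})

test_that("the configuration-stratified model agrees with the cohort model when they coincide", {
  # a single (fully informative) configuration per cohort and full
  # detection: M2star's hierarchy collapses onto M2's
  specs <- list(cohort_spec("C1", c("2" = 40)), cohort_spec("C2", c("2" = 40)))
  pp <- generative_params("negative_binomial", beta_age = 0.002,
                          mu_cf = log(38), sigma2_cf = 0.004, omega = 1.8)
  sim <- simulate_cohorts(specs, pp, seed = 17)
  f_m2 <- fit_model(sim$meioses, model_spec("M2"),
                    mcmc = fast_mcmc(seed = 3, n_draws = 1500), monitor_alpha = FALSE)
  f_star <- fit_model(sim$meioses, model_spec("M2star"),
                      mcmc = fast_mcmc(seed = 4, n_draws = 1500), monitor_alpha = FALSE)
  expect_identical(f_star$data$K, f_m2$data$K)
  d2 <- pooled_draws(f_m2, "beta_age"); ds <- pooled_draws(f_star, "beta_age")
  mcse <- sqrt(sd(d2)^2 / coda::effectiveSize(f_m2$samples[, "beta_age"]) +
                 sd(ds)^2 / coda::effectiveSize(f_star$samples[, "beta_age"]))
  expect_lt(abs(median(d2) - median(ds)), 5 * mcse)
  expect_lt(abs(sd(d2) - sd(ds)) / sd(d2), 0.35)
})

test_that("adding partially informative meioses tightens the age-effect posterior", {
  specs <- lapply(1:4, function(i) {
    cohort_spec(paste0("C", i), c("2" = 40, "4" = 60), age_mean = 28)
  })
  pp <- generative_params("negative_binomial", beta_age = 0.002,
                          mu_cf = log(38), sigma2_cf = 0.004, omega = 1.9)
  sim <- simulate_cohorts(specs, pp, seed = 19)
  f_full <- fit_model(sim$meioses, model_spec("M2"),
                      mcmc = fast_mcmc(seed = 5, n_draws = 1500),
                      monitor_alpha = FALSE)
  f_star <- fit_model(sim$meioses, model_spec("M2star"),
                      mcmc = fast_mcmc(seed = 6, n_draws = 1500),
                      monitor_alpha = FALSE)
  expect_gt(f_star$data$N, f_full$data$N)
  w <- function(f) diff(unname(posterior_quantile(f, "beta_age", c(0.025, 0.975))))
  expect_lt(w(f_star), w(f_full))
})

test_that("per-cohort age-effect models expose the cohort effects and their hierarchy", {
  specs <- list(cohort_spec("C1", c("2" = 30)), cohort_spec("C2", c("2" = 30)))
  sim <- simulate_cohorts(specs, default_generative_params(specs), seed = 23)
  f <- fit_model(sim$meioses, model_spec("M1.2"), mcmc = fast_mcmc(seed = 7),
                 monitor_alpha = FALSE)
  pars <- colnames(f$samples[[1]])
  expect_true(all(c("beta_age[C1]", "beta_age[C2]", "beta_age_global",
                    "sigma2_beta") %in% pars))
  # cohort effects shrink towards the global effect
  bg <- median(pooled_draws(f, "beta_age_global"))
  b1 <- median(pooled_draws(f, "beta_age[C1]"))
  expect_lt(abs(b1 - bg), 0.5)
})

test_that("non-convergence is reported with the offending R-hats", {
  specs <- list(cohort_spec("C1", c("2" = 20)), cohort_spec("C2", c("2" = 20)))
  sim <- simulate_cohorts(specs, default_generative_params(specs), seed = 29)
  # 40 draws cannot pass a 1.001 threshold: the error must carry R-hats
  expect_error(
    fit_model(sim$meioses, model_spec("M2"),
              mcmc = mcmc_control(n_chains = 2, n_draws = 40, seed = 1,
                                  n_adapt = 50, rhat_threshold = 1.0001,
                                  max_extensions = 0),
              monitor_alpha = FALSE),
    "R-hat")
})

test_that("prior-robustness reruns preserve the qualitative inference", {
  specs <- lapply(1:3, function(i) cohort_spec(paste0("C", i), c("2" = 40, "4" = 50)))
  # strong positive effect so every rerun should conclude beta > 0
  pp <- generative_params("negative_binomial", beta_age = 0.02,
                          mu_cf = log(38) - 0.02 * 28, sigma2_cf = 0.004,
                          omega = 1.9)
  sim <- simulate_cohorts(specs, pp, seed = 31)
  # scaled draw counts: slow-mixing relaxed variance priors may warn
  suppressWarnings(
    rr <- robustness_reruns(sim$meioses, model_spec("M2star"),
                            mcmc = fast_mcmc(seed = 8, n_draws = 800),
                            monitor_alpha = FALSE)
  )
  expect_length(rr, 4L)
  expect_named(rr, c("beta_age", "mu", "sigma", "omega"))
  expect_true(all(attr(rr, "pr_positive") >= 0.99))
  expect_error(robustness_reruns(sim$meioses, model_spec("M2")), "M2star")
})
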