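# Shared builders for test fixtures (all data is generated in code).

# a minimal meiosis-table row set
make_meioses <- function(cohort, parent, child, age, count, configuration = 4L,
                         sex = "F", family = NULL) {
  data.frame(cohort = cohort,
             family_id = if (is.null(family)) paste0("fam_", parent) else family,
             parent_id = parent, child_id = child, parent_sex = sex,
             parent_age_years = age, configuration = configuration,
             n_crossovers = count, stringsAsFactors = FALSE)
}

make_call <- function(parent, child, chrom, left, right, p = 0.9, cohort = "T") {
  data.frame(cohort = cohort, parent_id = parent, child_id = child,
             chrom = chrom, start_bp = left * 1000, end_bp = right * 1000,
             posterior_prob = p, left_snp_index = left, right_snp_index = right,
             stringsAsFactors = FALSE)
}

# A 20-call toy table for one cohort with X = 50: 12 well-separated genuine
# calls, 3 tight pairs (inner separation < 50), and 2 low-confidence calls
# (P <= 0.5). After thresholding and the double-crossover filter exactly
# the 12 genuine calls survive.
toy_call_table <- function() {
  good <- do.call(rbind, lapply(seq_len(6), function(i) {
    make_call("P1", "C1", "chr1", 1000 * i, 1000 * i + 1)
  }))
  good2 <- do.call(rbind, lapply(seq_len(6), function(i) {
    make_call("P2", "C2", "chr1", 1500 * i, 1500 * i + 1)
  }))
  tight <- rbind(
    make_call("P1", "C1", "chr2", 500, 501), make_call("P1", "C1", "chr2", 530, 531),
    make_call("P1", "C1", "chr3", 700, 701), make_call("P1", "C1", "chr3", 740, 741),
    make_call("P2", "C2", "chr2", 900, 901), make_call("P2", "C2", "chr2", 902, 903)
  )
  lowp <- rbind(
    make_call("P1", "C1", "chr4", 5000, 5001, p = 0.3),
    make_call("P2", "C2", "chr4", 6000, 6001, p = 0.5)
  )
  rbind(good, good2, tight, lowp)
}

# two-cohort fully informative design for calibration tests
calibration_design <- function(mothers_per_cohort = 40, seed = 5) {
  specs <- list(
    cohort_spec("C1", c("2" = mothers_per_cohort), age_mean = 28, age_sd = 5),
    cohort_spec("C2", c("2" = mothers_per_cohort), age_mean = 28, age_sd = 5)
  )
  params <- generative_params("normal", beta_age = 0.08, mu_cf = 38,
                              sigma2_cf = 3, tau2 = 6)
  simulate_cohorts(specs, params, seed = seed)$meioses
}

# build a minimal posterior_draws object around given draws (2 chains)
fake_fit <- function(draws, parameter = "beta_age", likelihood = "normal") {
  n <- length(draws)
  half <- split(draws, rep(1:2, each = ceiling(n / 2))[seq_len(n)])
  samples <- coda::mcmc.list(lapply(half, function(d) {
    coda::mcmc(matrix(d, ncol = 1, dimnames = list(NULL, parameter)))
  }))
  structure(list(samples = samples, rhat = c(1), spec = list(likelihood = likelihood),
                 fixed = list(), relaxed = "none", monitor_alpha = FALSE),
            class = "posterior_draws")
}

# reduced MCMC settings for fast tests
fast_mcmc <- function(seed = 1, n_draws = 1000, n_chains = 2) {
  mcmc_control(n_chains = n_chains, n_draws = n_draws, seed = seed,
               n_adapt = 200, max_extensions = 1, on_nonconvergence = "warn")
}
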