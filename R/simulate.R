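# Multi-cohort synthetic-data generator: pedigrees, parental ages, true
# crossover counts and call-level tables with injected artifacts.

#' Describe one cohort for the synthetic-data generator
#'
#' A cohort specification controls how many families of each of the six
#' family configurations are simulated, the maternal age distribution, the
#' paternal age offset, and the cohort's SNP density (which drives the
#' double-crossover filter threshold downstream).
#'
#' Family configurations follow the pedigree shapes used for crossover
#' calling: families with at least three children and one or both genotyped
#' parents (configurations 1 and 2), families with two children and one or
#' both parents (3 and 4), and families with two children, the grandparents
#' on the side of the transmitting parent, and one or both parents (5 and 6).
#' Configurations 2 and 6 are fully informative; the rest are partially
#' informative.
#'
#' @param cohort_id Character label for the cohort.
#' @param n_families Named integer vector mapping configuration codes
#'   (`"1"`..`"6"`) to the number of families to simulate; missing codes
#'   default to 0.
#' @param age_mean,age_sd Mean and standard deviation (years) of the
#'   truncated-normal distribution of maternal age at a child's birth.
#' @param age_min,age_max Truncation bounds (years); `age_min < age_max`.
#' @param paternal_age_offset Years added to the maternal age when paternal
#'   meioses are simulated.
#' @param snps_per_mb Average number of SNPs per megabase for the cohort;
#'   positive. Used as the X threshold of the double-crossover filter.
#' @return An object of class `"cohort_spec"`.
#' @seealso [simulate_cohorts()], [default_cohort_specs()]
#' @export
cohort_spec <- function(cohort_id,
                        n_families = c("2" = 20, "4" = 20),
                        age_mean = 28, age_sd = 5,
                        age_min = 16, age_max = 45,
                        paternal_age_offset = 3,
                        snps_per_mb = 250) {
  stopifnot(is.character(cohort_id), length(cohort_id) == 1L, nzchar(cohort_id))
  nf <- n_families
  if (is.null(names(nf)) || !all(names(nf) %in% as.character(1:6))) {
    stop("`n_families` must be named with configuration codes in 1..6", call. = FALSE)
  }
  if (any(nf < 0)) stop("family counts must be >= 0", call. = FALSE)
  if (!(age_sd > 0)) stop("`age_sd` must be > 0", call. = FALSE)
  if (!(age_min < age_max)) stop("`age_min` must be < `age_max`", call. = FALSE)
  if (!(snps_per_mb > 0)) stop("`snps_per_mb` must be > 0", call. = FALSE)
  full <- stats::setNames(rep(0L, 6L), as.character(1:6))
  full[names(nf)] <- as.integer(nf)
  structure(
    list(cohort_id = cohort_id, n_families = full,
         age_mean = age_mean, age_sd = age_sd,
         age_min = age_min, age_max = age_max,
         paternal_age_offset = paternal_age_offset,
         snps_per_mb = snps_per_mb),
    class = "cohort_spec"
  )
}

#' Default nine-cohort study design
#'
#' Returns cohort specifications emulating the structure of a nine-cohort
#' SNP-chip consortium: heterogeneous cohort sizes (a handful of families up
#' to over a thousand meioses), families of two or more children spread over
#' the six configurations, cohort-specific SNP densities, and maternal age
#' distributions centred in the late twenties. Sizes are loosely proportional
#' to the published multi-cohort designs of this kind; they are defaults for
#' simulation studies, not canonical values.
#'
#' @param scale Multiplier applied to all family counts (rounded up); use
#'   `scale < 1` for quick tests.
#' @return A list of [cohort_spec()] objects.
#' @export
default_cohort_specs <- function(scale = 1) {
  base <- list(
    list("Carlantino",  c("1" = 1,  "2" = 2,  "3" = 4,  "4" = 6,  "5" = 2,  "6" = 3),  29, 230),
    list("FrenchCan",   c("1" = 4,  "2" = 25, "3" = 10, "4" = 25, "5" = 6,  "6" = 10), 27, 210),
    list("FVG",         c("1" = 2,  "2" = 4,  "3" = 12, "4" = 30, "5" = 8,  "6" = 14), 29, 240),
    list("NTR",         c("1" = 10, "2" = 86, "3" = 40, "4" = 180, "5" = 14, "6" = 30), 30, 260),
    list("ORCADES",     c("1" = 2,  "2" = 13, "3" = 18, "4" = 55, "5" = 8,  "6" = 13), 28, 220),
    list("QTR370",      c("1" = 20, "2" = 219, "3" = 20, "4" = 60, "5" = 30, "6" = 54), 28, 150),
    list("QTR610",      c("1" = 30, "2" = 373, "3" = 120, "4" = 600, "5" = 30, "6" = 49), 28, 250),
    list("QTRCoreExome", c("1" = 6, "2" = 69, "3" = 40, "4" = 180, "5" = 14, "6" = 23), 28, 140),
    list("ValBorbera",  c("1" = 1,  "2" = 8,  "3" = 20, "4" = 70, "5" = 8,  "6" = 16), 29, 240)
  )
  lapply(base, function(b) {
    cohort_spec(cohort_id = b[[1]],
                n_families = ceiling(b[[2]] * scale),
                age_mean = b[[3]], snps_per_mb = b[[4]])
  })
}

#' Generative parameters for the synthetic crossover model
#'
#' Holds the true parameters of the hierarchical generative process: the
#' per-year age effect `beta_age` (additive for the normal family, on the
#' log scale for the negative binomial), the mean and variance of the
#' parent effects per (cohort, configuration) cell, the residual variance
#' (normal family), the overdispersion `omega` (negative binomial;
#' `Var = omega * mean`), and the per-cell detection probability with which
#' each true crossover is observed.
#'
#' `mu_cf`, `sigma2_cf` and `detection_prob_cf` may each be a single number
#' (recycled over all cells) or a data frame with columns `cohort`,
#' `configuration`, `value`. Detection must equal 1 for the fully
#' informative configurations 2 and 6.
#'
#' @param model_family `"normal"` or `"negative_binomial"`.
#' @param beta_age Per-year age effect.
#' @param mu_cf Mean of the parent effects per (cohort, configuration).
#' @param sigma2_cf Variance of the parent effects per cell; `>= 0`.
#' @param tau2 Residual variance (normal family only); `>= 0`.
#' @param omega Overdispersion (negative-binomial family only); `>= 1`,
#'   `omega = 1` falls back to Poisson emission.
#' @param detection_prob_cf Probability in (0, 1] that a true crossover is
#'   called.
#' @return An object of class `"generative_params"`.
#' @export
generative_params <- function(model_family = c("negative_binomial", "normal"),
                              beta_age = 0,
                              mu_cf = if (model_family[1] == "normal") 38 else log(38),
                              sigma2_cf = if (model_family[1] == "normal") 4 else 0.005,
                              tau2 = NULL, omega = NULL,
                              detection_prob_cf = 1) {
  model_family <- match.arg(model_family)
  if (model_family == "normal") {
    if (is.null(tau2)) tau2 <- 25
    if (!is.null(omega)) stop("`omega` applies to the negative-binomial family only", call. = FALSE)
    if (!(tau2 >= 0)) stop("`tau2` must be >= 0", call. = FALSE)
  } else {
    if (is.null(omega)) omega <- 1.9
    if (!is.null(tau2)) stop("`tau2` applies to the normal family only", call. = FALSE)
    if (!(omega >= 1)) stop("`omega` must be >= 1", call. = FALSE)
  }
  for (nm in c("mu_cf", "sigma2_cf", "detection_prob_cf")) {
    v <- get(nm)
    if (!(is.numeric(v) && length(v) == 1L) && !is.data.frame(v)) {
      stop(sprintf("`%s` must be a single number or a (cohort, configuration, value) data frame", nm),
           call. = FALSE)
    }
  }
  sig_vals <- if (is.data.frame(sigma2_cf)) sigma2_cf$value else sigma2_cf
  if (any(sig_vals < 0)) stop("`sigma2_cf` values must be >= 0", call. = FALSE)
  det_vals <- if (is.data.frame(detection_prob_cf)) detection_prob_cf$value else detection_prob_cf
  if (any(det_vals <= 0 | det_vals > 1)) {
    stop("detection probabilities must lie in (0, 1]", call. = FALSE)
  }
  if (is.data.frame(detection_prob_cf)) {
    fully <- detection_prob_cf$configuration %in% c(2L, 6L)
    if (any(detection_prob_cf$value[fully] != 1)) {
      stop("detection probability must be 1 for fully informative configurations (2 and 6)",
           call. = FALSE)
    }
  }
  structure(
    list(model_family = model_family, beta_age = beta_age,
         mu_cf = mu_cf, sigma2_cf = sigma2_cf, tau2 = tau2, omega = omega,
         detection_prob_cf = detection_prob_cf),
    class = "generative_params"
  )
}

#' Default generative parameters
#'
#' Negative-binomial truth with a small positive maternal age effect
#' (0.00213 per year on the log scale, i.e. a multiplicative factor of about
#' 1.0021 per year), a baseline of about 38 maternal crossovers at the
#' typical maternal age, modest between-mother variation, overdispersion
#' `omega = 1.9`, full detection in the fully informative configurations
#' and 90% detection elsewhere (emulating under-calling in partially
#' informative meioses).
#'
#' @param specs Optional list of [cohort_spec()] objects used to lay out the
#'   per-cell detection table; defaults to [default_cohort_specs()].
#' @return A [generative_params()] object.
#' @export
default_generative_params <- function(specs = default_cohort_specs()) {
  cohorts <- vapply(specs, function(s) s$cohort_id, character(1))
  det <- expand.grid(cohort = cohorts, configuration = 1:6,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  det$value <- ifelse(det$configuration %in% c(2L, 6L), 1, 0.9)
  beta <- 0.00213
  generative_params(
    model_family = "negative_binomial",
    beta_age = beta,
    mu_cf = log(38) - beta * 28,   # baseline ~38 crossovers at age 28
    sigma2_cf = 0.005,
    omega = 1.9,
    detection_prob_cf = det
  )
}

# deterministic string hash (order-independent cohort seeding)
.str_hash <- function(x) {
  v <- utf8ToInt(x)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 2147483563
  as.integer(h)
}

# look up a per-(cohort, configuration) value from a scalar or a map
.cf_value <- function(map, cohort, configuration) {
  if (is.numeric(map) && length(map) == 1L) return(unname(map))
  i <- which(map$cohort == cohort & map$configuration == configuration)
  if (length(i) != 1L) {
    stop(sprintf("no value for cohort '%s', configuration %d", cohort, configuration),
         call. = FALSE)
  }
  map$value[i]
}

# truncated-normal draw by rejection with a uniform fallback
.rtruncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stats::runif(1, lo, hi)
}

#' Simulate multi-cohort crossover-count data
#'
#' Generates, for each cohort, families in the requested configurations;
#' draws each parent's baseline effect `alpha ~ N(mu_cf, sigma2_cf)`; draws
#' parental ages at each birth from a truncated normal with inter-birth
#' intervals of at least one year (ages strictly increase with birth
#' order); emits true crossover counts from the generative family (normal:
#' `round(max(0, N(beta_age * age + alpha, tau2)))`; negative binomial:
#' mean `exp(beta_age * age + alpha)`, variance `omega` times the mean);
#' and thins them binomially with the per-cell detection probability.
#'
#' Randomness is streamed per cohort (seeded from a hash of the cohort id)
#' and split deterministically per family, so adding or reordering cohorts
#' does not perturb the data simulated for the others. The same seed and
#' inputs reproduce the output exactly.
#'
#' @param specs List of [cohort_spec()] objects (at least one).
#' @param params A [generative_params()] object.
#' @param seed Integer seed.
#' @param parent_sex `"F"` for maternal meioses (default) or `"M"` for
#'   paternal (ages get the cohort's paternal offset).
#' @return A list with components `meioses` (data frame with columns
#'   `cohort`, `family_id`, `parent_id`, `child_id`, `parent_sex`,
#'   `parent_age_years`, `configuration`, `n_crossovers`) and `truth`
#'   (class `"simulation_truth"`: the generative parameters, per-parent
#'   effects, true counts per meiosis, per-cohort SNP densities, and the
#'   seed).
#' @export
simulate_cohorts <- function(specs, params, seed, parent_sex = c("F", "M")) {
  parent_sex <- match.arg(parent_sex)
  if (inherits(specs, "cohort_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L)
  if (!inherits(params, "generative_params")) stop("`params` must be a generative_params object", call. = FALSE)
  seed <- as.integer(seed)

  rows <- list(); effects <- list(); trues <- list()
  for (sp in specs) {
    if (!inherits(sp, "cohort_spec")) stop("each spec must be a cohort_spec", call. = FALSE)
    cohort_seed <- (abs(seed) + .str_hash(sp$cohort_id)) %% 2147483563
    fam_idx <- 0L
    for (cf in 1:6) {
      nfam <- sp$n_families[[as.character(cf)]]
      if (nfam == 0L) next
      mu <- .cf_value(params$mu_cf, sp$cohort_id, cf)
      s2 <- .cf_value(params$sigma2_cf, sp$cohort_id, cf)
      pdet <- .cf_value(params$detection_prob_cf, sp$cohort_id, cf)
      if (pdet <= 0 || pdet > 1) stop("detection probability outside (0, 1]", call. = FALSE)
      for (f in seq_len(nfam)) {
        fam_idx <- fam_idx + 1L
        set.seed((cohort_seed + 104729 * fam_idx) %% 2147483563)
        n_children <- if (cf %in% c(1L, 2L)) 3L + stats::rbinom(1L, 2L, 0.15) else 2L
        alpha <- stats::rnorm(1, mu, sqrt(s2))
        # mother's age at first birth; intervals >= 1 year
        a1 <- .rtruncnorm1(sp$age_mean - 1.25 * (n_children - 1), sp$age_sd,
                           sp$age_min, sp$age_max)
        gaps <- 1 + stats::rexp(n_children - 1L, rate = 1 / 1.5)
        ages <- a1 + cumsum(c(0, gaps))
        if (ages[n_children] > sp$age_max) {
          gaps <- rep(1, n_children - 1L)
          ages <- a1 + cumsum(c(0, gaps))
          if (ages[n_children] > sp$age_max) {
            ages <- (sp$age_max - (n_children - 1L)) + cumsum(c(0, gaps))
          }
        }
        if (parent_sex == "M") ages <- ages + sp$paternal_age_offset
        family_id <- sprintf("%s_F%05d", sp$cohort_id, fam_idx)
        parent_id <- sprintf("%s_P%05d", sp$cohort_id, fam_idx)
        eta <- params$beta_age * ages + alpha
        y_true <- if (params$model_family == "normal") {
          pmax(0, round(stats::rnorm(n_children, eta, sqrt(params$tau2))))
        } else if (params$omega == 1) {
          stats::rpois(n_children, exp(eta))
        } else {
          m <- exp(eta)
          stats::rnbinom(n_children, size = m / (params$omega - 1), prob = 1 / params$omega)
        }
        y_obs <- stats::rbinom(n_children, y_true, pdet)
        child_ids <- sprintf("%s_C%d", family_id, seq_len(n_children))
        rows[[length(rows) + 1L]] <- data.frame(
          cohort = sp$cohort_id, family_id = family_id, parent_id = parent_id,
          child_id = child_ids, parent_sex = parent_sex,
          parent_age_years = ages, configuration = cf, n_crossovers = y_obs,
          stringsAsFactors = FALSE
        )
        effects[[parent_id]] <- alpha
        trues[[length(trues) + 1L]] <- data.frame(
          parent_id = parent_id, child_id = child_ids, true_count = y_true,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  meioses <- do.call(rbind, rows)
  rownames(meioses) <- NULL
  truth <- structure(
    list(params = params,
         parent_effects = unlist(effects),
         true_counts = do.call(rbind, trues),
         snps_per_mb = stats::setNames(
           vapply(specs, function(s) s$snps_per_mb, numeric(1)),
           vapply(specs, function(s) s$cohort_id, character(1))),
         seed = seed),
    class = "simulation_truth"
  )
  list(meioses = meioses, truth = truth)
}

#' Expand a meiosis table into a raw crossover-call table
#'
#' Each called crossover in the meiosis table becomes one row with a genomic
#' interval, flanking SNP indices and a posterior probability drawn above
#' 0.5. Genuine consecutive calls on the same chromosome are spaced at
#' least X SNPs apart (X is the cohort's SNPs-per-megabase density), so
#' they survive the double-crossover filter. Optionally, artifacts are
#' injected: with probability `artifact_rate` per meiosis, a pair of
#' spurious calls separated by fewer than X SNPs; with probability
#' `low_conf_rate` per meiosis, a low-confidence call with `P <= 0.5`.
#' Injected artifact coordinates are recorded in the `"injected"` attribute
#' so downstream filters can be scored against the truth ledger.
#'
#' @param meioses Meiosis table from [simulate_cohorts()].
#' @param truth The matching `"simulation_truth"` object (supplies the
#'   per-cohort SNP densities and is checked for consistency).
#' @param artifact_rate Probability in `[0, 1)` of injecting one tight
#'   spurious pair into a meiosis.
#' @param seed Integer seed.
#' @param low_conf_rate Probability in `[0, 1)` of injecting one
#'   low-confidence (`P <= 0.5`) call into a meiosis.
#' @return A call table (columns `cohort`, `parent_id`, `child_id`,
#'   `chrom`, `start_bp`, `end_bp`, `posterior_prob`, `left_snp_index`,
#'   `right_snp_index`) with attribute `"injected"` describing artifacts.
#' @export
simulate_call_table <- function(meioses, truth, artifact_rate = 0, seed = 1,
                                low_conf_rate = 0) {
  if (!inherits(truth, "simulation_truth")) stop("`truth` must be a simulation_truth", call. = FALSE)
  if (artifact_rate < 0 || artifact_rate >= 1) stop("`artifact_rate` must be in [0, 1)", call. = FALSE)
  if (low_conf_rate < 0 || low_conf_rate >= 1) stop("`low_conf_rate` must be in [0, 1)", call. = FALSE)
  if (!all(meioses$cohort %in% names(truth$snps_per_mb))) {
    stop("meiosis table and truth ledger do not match (unknown cohorts)", call. = FALSE)
  }
  key_m <- paste(meioses$parent_id, meioses$child_id)
  key_t <- paste(truth$true_counts$parent_id, truth$true_counts$child_id)
  if (!all(key_m %in% key_t)) {
    stop("meiosis table and truth ledger do not match (unknown meioses)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  calls <- list(); injected <- list()
  for (i in seq_len(nrow(meioses))) {
    row <- meioses[i, ]
    x <- truth$snps_per_mb[[row$cohort]]
    n <- row$n_crossovers
    max_idx_by_chrom <- integer(0)
    if (n > 0) {
      chroms <- sort(sample(1:22, n, replace = TRUE))
      for (ch in unique(chroms)) {
        k <- sum(chroms == ch)
        start <- sample(1000:5000, 1)
        gaps <- ceiling(x) + sample(50:2000, k, replace = TRUE)
        left <- start + cumsum(gaps) - gaps[1]
        right <- left + 1L
        calls[[length(calls) + 1L]] <- data.frame(
          cohort = row$cohort, parent_id = row$parent_id, child_id = row$child_id,
          chrom = paste0("chr", ch),
          start_bp = round(left / x * 1e6), end_bp = round(right / x * 1e6),
          posterior_prob = stats::runif(k, 0.5 + 1e-6, 1),
          left_snp_index = left, right_snp_index = right,
          stringsAsFactors = FALSE
        )
        max_idx_by_chrom[as.character(ch)] <- max(right)
      }
    }
    if (artifact_rate > 0 && stats::runif(1) < artifact_rate) {
      ch <- sample(1:22, 1)
      base <- if (as.character(ch) %in% names(max_idx_by_chrom)) {
        max_idx_by_chrom[[as.character(ch)]] + ceiling(x) + 1000L
      } else sample(1000:5000, 1)
      sep <- sample(0:max(0, ceiling(x) - 2L), 1)
      l1 <- base; r1 <- l1 + 1L; l2 <- r1 + sep; r2 <- l2 + 1L
      pair <- data.frame(
        cohort = row$cohort, parent_id = row$parent_id, child_id = row$child_id,
        chrom = paste0("chr", ch),
        start_bp = round(c(l1, l2) / x * 1e6), end_bp = round(c(r1, r2) / x * 1e6),
        posterior_prob = stats::runif(2, 0.5 + 1e-6, 1),
        left_snp_index = c(l1, l2), right_snp_index = c(r1, r2),
        stringsAsFactors = FALSE
      )
      calls[[length(calls) + 1L]] <- pair
      injected[[length(injected) + 1L]] <- cbind(pair[, c("parent_id", "child_id", "chrom",
                                                          "left_snp_index", "right_snp_index")],
                                                 type = "tight_pair")
    }
    if (low_conf_rate > 0 && stats::runif(1) < low_conf_rate) {
      ch <- sample(1:22, 1)
      base <- if (as.character(ch) %in% names(max_idx_by_chrom)) {
        max_idx_by_chrom[[as.character(ch)]] + 2L * ceiling(x) + 5000L
      } else sample(1000:5000, 1)
      lc <- data.frame(
        cohort = row$cohort, parent_id = row$parent_id, child_id = row$child_id,
        chrom = paste0("chr", ch),
        start_bp = round(base / x * 1e6), end_bp = round((base + 1L) / x * 1e6),
        posterior_prob = stats::runif(1, 0.05, 0.5),
        left_snp_index = base, right_snp_index = base + 1L,
        stringsAsFactors = FALSE
      )
      calls[[length(calls) + 1L]] <- lc
      injected[[length(injected) + 1L]] <- cbind(lc[, c("parent_id", "child_id", "chrom",
                                                        "left_snp_index", "right_snp_index")],
                                                 type = "low_prob")
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else data.frame(
    cohort = character(0), parent_id = character(0), child_id = character(0),
    chrom = character(0), start_bp = numeric(0), end_bp = numeric(0),
    posterior_prob = numeric(0), left_snp_index = integer(0),
    right_snp_index = integer(0), stringsAsFactors = FALSE
  )
  out <- out[order(out$cohort, out$parent_id, out$child_id, out$chrom, out$left_snp_index), ]
  rownames(out) <- NULL
  attr(out, "injected") <- if (length(injected)) do.call(rbind, injected) else NULL
  out
}
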