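# Hierarchical-model specifications and empirical-Bayes prior construction.

.model_table <- data.frame(
  model_id = c("M1", "M1.2", "M2", "M2.2", "M2star", "M2.2star"),
  likelihood = c("normal", "normal", "negative_binomial", "negative_binomial",
                 "negative_binomial", "negative_binomial"),
  age_effect = c("common", "per_cohort", "common", "per_cohort",
                 "common", "per_cohort"),
  hierarchy_level = c("cohort", "cohort", "cohort", "cohort",
                      "cohort_by_configuration", "cohort_by_configuration"),
  stringsAsFactors = FALSE
)

#' Specify a Bayesian hierarchical model
#'
#' Six models are available. `M1`/`M1.2` place a normal likelihood on the
#' counts with an additive per-year age effect; `M2`/`M2.2` use a negative
#' binomial likelihood with an exponential link, so the expected count is
#' multiplied by `exp(beta_age)` per year and `Var(Y) = omega * E(Y)`.
#' The `.2` variants draw a cohort-specific age effect `beta_age_c` from a
#' common normal distribution instead of sharing a single `beta_age`.
#' `M1`-`M2.2` put the parent-effect hierarchy at cohort level and are
#' fitted to fully informative meioses (configurations 2 and 6); `M2star`
#' and `M2.2star` stratify the parent-effect means and variances by
#' (cohort, family configuration), absorbing configuration-dependent
#' under-calling, and are fitted to all families with two or more
#' children.
#'
#' @param model_id One of `"M1"`, `"M1.2"`, `"M2"`, `"M2.2"`, `"M2star"`,
#'   `"M2.2star"`.
#' @param parent_sex `"F"` (maternal) or `"M"` (paternal); controls the
#'   default prior centring in [build_priors()] and which meioses are
#'   selected.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(model_id = c("M1", "M1.2", "M2", "M2.2", "M2star", "M2.2star"),
                       parent_sex = c("F", "M")) {
  model_id <- match.arg(model_id)
  parent_sex <- match.arg(parent_sex)
  row <- .model_table[.model_table$model_id == model_id, ]
  structure(
    list(model_id = model_id,
         likelihood = row$likelihood,
         age_effect = row$age_effect,
         hierarchy_level = row$hierarchy_level,
         parent_sex = parent_sex),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model %s: %s likelihood, %s age effect, %s hierarchy, %s meioses\n",
              x$model_id, x$likelihood, x$age_effect,
              gsub("_", " ", x$hierarchy_level),
              if (x$parent_sex == "F") "maternal" else "paternal"))
  invisible(x)
}

# subset a meiosis table to the stratum the model is defined on, and apply
# the minimum-meioses exclusion rule at the matching level
.model_subset <- function(meioses, spec, min_meioses = 20) {
  m <- meioses[meioses$parent_sex == spec$parent_sex, , drop = FALSE]
  if (spec$hierarchy_level == "cohort") {
    m <- m[m$configuration %in% c(2L, 6L), , drop = FALSE]
  }
  # parents with a single meiosis carry no information about their own effect
  tab <- table(m$parent_id)
  m <- m[m$parent_id %in% names(tab)[tab >= 2L], , drop = FALSE]
  m <- apply_exclusion_rules(m, min_meioses = min_meioses,
                             per_configuration =
                               spec$hierarchy_level == "cohort_by_configuration")
  rownames(m) <- NULL
  m
}

# inverse-gamma quantile: X ~ IG(shape, scale) <=> 1/X ~ Gamma(shape, rate = scale)
.qinvgamma <- function(p, shape, scale) {
  scale / stats::qgamma(1 - p, shape)
}

.dinvgamma_log <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

# choose an inverse-gamma (shape, scale) whose mean equals mean(v) and whose
# central 95% interval covers range(v); the shape starts at 3 and is relaxed
# towards 1 (widening the distribution while keeping the mean matched) if the
# coverage constraint is not met at shape 3
.eb_invgamma <- function(v, shape_start = 3) {
  v <- v[is.finite(v) & v > 0]
  if (length(v) == 0L) stop("no positive empirical variances to calibrate against", call. = FALSE)
  m <- mean(v)
  shape <- shape_start
  repeat {
    scale <- (shape - 1) * m
    lo <- .qinvgamma(0.025, shape, scale)
    hi <- .qinvgamma(0.975, shape, scale)
    if ((lo <= min(v) && hi >= max(v)) || shape <= 1.2) break
    shape <- shape - 0.2
  }
  list(shape = shape, scale = scale)
}

#' Construct the prior set for a hierarchical model
#'
#' Builds the priors the models are fitted with, partly by empirical
#' Bayes:
#' * `beta_age ~ N(0, 1)` (previously reported effects ranged from about
#'   -0.5 to +0.2 crossovers per year, so this is weakly informative).
#' * The cell means `mu` get a normal prior centred at 41 crossovers for
#'   maternal fits with the normal likelihood -- or `log(41) ~= 3.7` under
#'   the exponential link of the negative binomial -- with a large
#'   variance (100). Paternal fits are centred at the empirical mean
#'   count (log-transformed for the negative binomial).
#' * The parent-effect variances `sigma2` get an inverse-gamma prior whose
#'   mean matches the average of the empirical variances of per-parent
#'   mean counts across cohorts (log scale for the negative binomial) and
#'   whose central 95% interval covers all of them; the shape starts at 3
#'   and is relaxed towards 1 if coverage requires it.
#' * The residual variance `tau2` (normal likelihood only) gets an
#'   inverse-gamma prior with mean equal to the empirical variance of the
#'   counts across fully informative meioses.
#' * `omega^{-1} ~ U(0, 1)` (negative binomial only), constraining the
#'   overdispersion to `(1, Inf)`.
#' * Per-cohort age-effect models add `beta_age_global ~ N(0, 1)` and an
#'   inverse-gamma prior on the between-cohort effect variance with mean
#'   0.01 (a spread of about 0.1 crossovers/year between cohorts).
#'
#' @param meioses Meiosis table (before or after [`.model_subset`][fit_model]
#'   subsetting; the function subsets internally).
#' @param spec A [model_spec()].
#' @param mu_mean_maternal Prior mean count for maternal fits; default 41.
#' @param sigma2_shape_start Starting inverse-gamma shape; default 3.
#' @param sigma2_beta_mean Prior mean of the between-cohort age-effect
#'   variance; default `0.1^2`.
#' @return An object of class `"prior_set"`.
#' @export
build_priors <- function(meioses, spec, mu_mean_maternal = 41,
                         sigma2_shape_start = 3, sigma2_beta_mean = 0.01) {
  m <- .model_subset(meioses, spec)
  if (nrow(m) == 0L) stop("no meioses left after model subsetting", call. = FALSE)
  nb <- spec$likelihood == "negative_binomial"

  if (spec$parent_sex == "F") {
    mu_mean <- if (nb) log(mu_mean_maternal) else mu_mean_maternal
  } else {
    emp <- mean(m$n_crossovers)
    mu_mean <- if (nb) log(emp) else emp
  }

  # empirical variances of per-parent mean counts, per hierarchy group
  pm <- stats::aggregate(n_crossovers ~ parent_id + cohort + configuration,
                         data = m, FUN = mean)
  if (nb) pm$n_crossovers <- log(pmax(pm$n_crossovers, 0.5))
  grp <- if (spec$hierarchy_level == "cohort") pm$cohort else
    paste(pm$cohort, pm$configuration)
  if (length(unique(m$cohort)) < 2L) {
    stop("need at least 2 cohorts to construct the sigma2 hyperprior", call. = FALSE)
  }
  vs <- tapply(pm$n_crossovers, grp, stats::var)
  vs <- vs[!is.na(vs)]
  s2 <- .eb_invgamma(as.numeric(vs), shape_start = sigma2_shape_start)

  tau2_shape <- NULL; tau2_scale <- NULL
  if (!nb) {
    fully <- m[m$configuration %in% c(2L, 6L), , drop = FALSE]
    if (nrow(fully) < 2L) fully <- m
    vtau <- stats::var(fully$n_crossovers)
    tau2_shape <- 3
    tau2_scale <- (tau2_shape - 1) * vtau  # prior mean = empirical count variance
  }

  structure(
    list(beta_mean = 0, beta_sd = 1,
         mu_mean = mu_mean, mu_var = 100,
         sigma2_shape = s2$shape, sigma2_scale = s2$scale,
         sigma2_empirical = as.numeric(vs),
         tau2_shape = tau2_shape, tau2_scale = tau2_scale,
         omega_inv_lower = if (nb) 0 else NULL,
         omega_inv_upper = if (nb) 1 else NULL,
         beta_global_mean = 0, beta_global_sd = 1,
         sigma2_beta_shape = 3, sigma2_beta_scale = 2 * sigma2_beta_mean),
    class = "prior_set"
  )
}

#' @export
print.prior_set <- function(x, ...) {
  cat("prior set:\n")
  cat(sprintf("  beta_age ~ N(%g, %g^2)\n", x$beta_mean, x$beta_sd))
  cat(sprintf("  mu ~ N(%.4g, %g)\n", x$mu_mean, x$mu_var))
  cat(sprintf("  sigma2 ~ InvGamma(shape %.3g, scale %.4g)\n",
              x$sigma2_shape, x$sigma2_scale))
  if (!is.null(x$tau2_shape)) {
    cat(sprintf("  tau2 ~ InvGamma(shape %.3g, scale %.4g)\n",
                x$tau2_shape, x$tau2_scale))
  }
  if (!is.null(x$omega_inv_lower)) {
    cat("  omega^-1 ~ U(0, 1)\n")
  }
  invisible(x)
}
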