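# Per-cohort linear mixed models with a parent random intercept, and
# inverse-variance fixed-effects meta-analysis across cohorts.

#' Fit the per-cohort linear mixed model
#'
#' Fits, by REML, the random-intercept model
#' `Y_ij = mu + beta_age * age_ij + alpha_j + eps_ij`, where `Y_ij` is the
#' crossover count for child `i` of parent `j`, `alpha_j ~ N(0, sigma2_alpha)`
#' is the parent's baseline deviation and `eps_ij ~ N(0, sigma2_eps)`.
#' Family size is deliberately not a covariate (the number of genotyped
#' children is not the true family size). The p-value is the two-sided
#' t-test on `beta_age`; the degrees of freedom follow the within-parent
#' residual convention (`n_meioses - n_parents - 1`), overridable via `df`.
#'
#' @param meioses Meiosis table for a single cohort; needs at least two
#'   parents, at least one parent with two or more children, and
#'   non-constant ages.
#' @param df Optional degrees of freedom for the t-test; defaults to the
#'   within-parent convention above.
#' @return A one-row data frame of class `"lmm_fit"`: `cohort`,
#'   `beta_age_hat`, `se_beta`, `mu_hat`, `sigma2_alpha_hat`,
#'   `sigma2_eps_hat`, `n_meioses`, `n_parents`, `df`, `t_value`, `p_value`.
#' @seealso [meta_fixed_effects()]
#' @export
fit_lmm <- function(meioses, df = NULL) {
  cohort <- unique(meioses$cohort)
  if (length(cohort) != 1L) stop("fit_lmm() expects meioses from a single cohort", call. = FALSE)
  if (length(unique(meioses$parent_id)) < 2L) {
    stop("need at least 2 parents to fit the mixed model", call. = FALSE)
  }
  if (max(table(meioses$parent_id)) < 2L) {
    stop("need at least one parent with 2 or more children", call. = FALSE)
  }
  if (stats::var(meioses$parent_age_years) == 0) {
    stop("singular design: all parental ages are identical", call. = FALSE)
  }
  dat <- data.frame(y = meioses$n_crossovers,
                    age = meioses$parent_age_years,
                    parent = factor(meioses$parent_id))
  fit <- tryCatch(
    nlme::lme(y ~ age, random = ~ 1 | parent, data = dat, method = "REML"),
    error = function(e) {
      # nlminb can fail on (near-)noise-free data; optim is more forgiving
      nlme::lme(y ~ age, random = ~ 1 | parent, data = dat, method = "REML",
                control = nlme::lmeControl(opt = "optim"))
    }
  )
  n <- nrow(dat)
  j <- nlevels(dat$parent)
  if (is.null(df)) df <- n - j - 1L
  beta <- unname(nlme::fixef(fit)["age"])
  se <- sqrt(stats::vcov(fit)["age", "age"])
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = df)
  vc <- nlme::VarCorr(fit)
  sigma2_alpha <- suppressWarnings(as.numeric(vc["(Intercept)", "Variance"]))
  out <- data.frame(
    cohort = cohort,
    beta_age_hat = beta, se_beta = se,
    mu_hat = unname(nlme::fixef(fit)["(Intercept)"]),
    sigma2_alpha_hat = max(sigma2_alpha, 0),
    sigma2_eps_hat = fit$sigma^2,
    n_meioses = n, n_parents = j, df = df,
    t_value = tval, p_value = pval,
    stringsAsFactors = FALSE
  )
  class(out) <- c("lmm_fit", "data.frame")
  out
}

#' Fixed-effects meta-analysis of per-cohort age-effect estimates
#'
#' Combines per-cohort `beta_age` estimates by inverse-variance weighting
#' (`w_i = 1 / se_i^2`), giving `beta = sum(w b) / sum(w)` with standard
#' error `(sum w)^{-1/2}`, a two-sided Z-test, and Cochran's Q test of
#' between-cohort homogeneity (`Q = sum w (b_i - beta)^2` on `k - 1`
#' degrees of freedom). Backed by a fixed-effect `metafor` fit.
#'
#' @param fits A data frame of per-cohort fits (rows of [fit_lmm()] bound
#'   together), or a list of them; needs at least two fits with finite
#'   standard errors.
#' @return A list of class `"meta_result"`: `beta_combined`, `se_combined`,
#'   `z`, `p_value`, `cochran_q`, `q_df`, `q_p_value`, `n_cohorts`.
#' @export
meta_fixed_effects <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits)) fits <- do.call(rbind, fits)
  if (nrow(fits) < 2L) stop("need at least 2 cohort fits to meta-analyse", call. = FALSE)
  if (any(!is.finite(fits$se_beta)) || any(!is.finite(fits$beta_age_hat))) {
    stop("non-finite estimate or standard error in the per-cohort fits", call. = FALSE)
  }
  rma <- metafor::rma(yi = fits$beta_age_hat, sei = fits$se_beta, method = "FE")
  out <- list(
    beta_combined = as.numeric(rma$beta),
    se_combined = rma$se,
    z = rma$zval,
    p_value = rma$pval,
    cochran_q = rma$QE,
    q_df = nrow(fits) - 1L,
    q_p_value = rma$QEp,
    n_cohorts = nrow(fits)
  )
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effects meta-analysis of %d cohorts\n", x$n_cohorts))
  cat(sprintf("  beta_age = %.4f (se %.4f), z = %.2f, p = %.3g\n",
              x$beta_combined, x$se_combined, x$z, x$p_value))
  cat(sprintf("  Cochran's Q = %.2f on %d df, p = %.3g\n",
              x$cochran_q, x$q_df, x$q_p_value))
  invisible(x)
}
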