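# Accessors and summaries for posterior_draws objects, the count-likelihood
# helper shared with the checks, and the per-draw log posterior used to
# locate the highest-posterior-density draw.

.parameter_names <- function(fit) colnames(fit$samples[[1L]])

#' Pooled posterior draws for one parameter
#'
#' Concatenates the post-burn-in draws of all chains.
#'
#' @param fit A `"posterior_draws"` object.
#' @param parameter Stored parameter name (see [fit_model()]).
#' @return Numeric vector of pooled draws.
#' @export
pooled_draws <- function(fit, parameter) {
  if (!(parameter %in% .parameter_names(fit))) {
    stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE)
  }
  unlist(lapply(fit$samples, function(ch) as.numeric(ch[, parameter])),
         use.names = FALSE)
}

#' Posterior quantile and positive-probability accessors
#'
#' `posterior_quantile()` evaluates the inverse empirical cumulative
#' distribution of a parameter's posterior at probabilities `q`;
#' `prob_positive()` returns the posterior probability that the parameter
#' is greater than zero.
#'
#' @param fit A `"posterior_draws"` object.
#' @param parameter Stored parameter name.
#' @param q Probabilities.
#' @return Quantiles (named) or a single probability.
#' @export
posterior_quantile <- function(fit, parameter, q) {
  stats::quantile(pooled_draws(fit, parameter), probs = q, names = TRUE)
}

#' @rdname posterior_quantile
#' @export
prob_positive <- function(fit, parameter) {
  mean(pooled_draws(fit, parameter) > 0)
}

#' Summarise one parameter's posterior
#'
#' Returns the 2.5/25/50/75/97.5% posterior quantiles and the posterior
#' probability of being positive. For age-effect parameters of
#' negative-binomial models the quantiles are reported for
#' `exp(beta_age)` -- the multiplicative per-year factor -- by default,
#' while `Pr(>0)` always refers to `beta_age` itself (equivalently,
#' `Pr(exp(beta_age) > 1)`).
#'
#' @param fit A `"posterior_draws"` object.
#' @param parameter Stored parameter name.
#' @param transform `"none"`, `"exp"`, or `NULL` (default) to pick `"exp"`
#'   automatically for age effects under a negative-binomial likelihood.
#' @return One-row data frame with columns `parameter`, `q2.5`, `q25`,
#'   `q50`, `q75`, `q97.5`, `pr_gt0`, `transform`.
#' @export
summarize_draws <- function(fit, parameter, transform = NULL) {
  d <- pooled_draws(fit, parameter)
  if (is.null(transform)) {
    transform <- if (fit$spec$likelihood == "negative_binomial" &&
                     grepl("^beta_age", parameter)) "exp" else "none"
  }
  transform <- match.arg(transform, c("none", "exp"))
  pr <- mean(d > 0)
  if (transform == "exp") d <- exp(d)
  qs <- stats::quantile(d, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  data.frame(parameter = parameter,
             q2.5 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4], q97.5 = qs[5],
             pr_gt0 = pr, transform = transform,
             stringsAsFactors = FALSE)
}

#' Negative-binomial count likelihood in (mean, overdispersion) form
#'
#' Probability mass of the count distribution with mean `mean` and
#' variance `omega * mean` (shape `a = mean / (omega - 1)`, success
#' probability `1 / omega`). At `omega = 1` the distribution is the
#' Poisson limit, which is returned exactly.
#'
#' @param y Non-negative integer counts.
#' @param mean Positive means (recycled against `y`).
#' @param omega Overdispersion, `>= 1`.
#' @param log Return log probabilities.
#' @return Probability masses (or their logs).
#' @export
dcount_nb <- function(y, mean, omega, log = FALSE) {
  if (any(omega < 1)) stop("`omega` must be >= 1", call. = FALSE)
  if (omega == 1) {
    stats::dpois(y, lambda = mean, log = log)
  } else {
    stats::dnbinom(y, size = mean / (omega - 1), prob = 1 / omega, log = log)
  }
}

# extract one pooled draw (by pooled index) as a named parameter set:
# beta per cell/cohort, mu and sigma2 per cell, tau2 or omega, alphas
.param_set <- function(fit, i) {
  ni <- nrow(fit$samples[[1L]])
  ch <- ((i - 1L) %/% ni) + 1L
  it <- ((i - 1L) %% ni) + 1L
  row <- fit$samples[[ch]][it, ]
  dd <- fit$data
  fx <- fit$fixed
  percoh <- fit$spec$age_effect == "per_cohort"
  beta_cell <- if (percoh) {
    as.numeric(row[sprintf("beta_age[%s]", dd$cells$cohort)])
  } else if (!is.null(fx$beta_age)) {
    rep(fx$beta_age, dd$K)
  } else {
    rep(as.numeric(row["beta_age"]), dd$K)
  }
  mu <- if (!is.null(fx$mu)) rep_len(fx$mu, dd$K) else
    as.numeric(row[sprintf("mu[%s]", dd$cells$label)])
  sigma2 <- if (!is.null(fx$sigma2)) rep_len(fx$sigma2, dd$K) else
    as.numeric(row[sprintf("sigma2[%s]", dd$cells$label)])
  nb <- fit$spec$likelihood == "negative_binomial"
  noise <- if (nb) {
    if (!is.null(fx$omega)) fx$omega else as.numeric(row["omega"])
  } else {
    if (!is.null(fx$tau2)) fx$tau2 else as.numeric(row["tau2"])
  }
  alpha <- if (dd$J > 0 && sprintf("alpha[%s]", dd$parent_ids[1]) %in% names(row)) {
    as.numeric(row[sprintf("alpha[%s]", dd$parent_ids)])
  } else NULL
  list(beta_cell = beta_cell, mu = mu, sigma2 = sigma2,
       noise = noise, alpha = alpha,
       beta_global = if (percoh) as.numeric(row["beta_age_global"]) else NULL,
       sigma2_beta = if (percoh) as.numeric(row["sigma2_beta"]) else NULL)
}

#' Per-draw unnormalized log posterior
#'
#' Evaluates, for every stored post-burn-in draw, the log likelihood of
#' the data plus the log prior and hyperprior densities, in the sampled
#' parameterization (flat-prior terms contribute constants and are
#' dropped). The per-parent effects must have been stored
#' (`monitor_alpha = TRUE`).
#'
#' @param fit A `"posterior_draws"` object.
#' @return Numeric vector, one value per pooled draw.
#' @seealso [map_draw()]
#' @export
log_posterior <- function(fit) {
  dd <- fit$data
  if (dd$J > 0 && !fit$monitor_alpha) {
    stop("log_posterior() needs stored parent effects; refit with monitor_alpha = TRUE",
         call. = FALSE)
  }
  pr <- fit$priors
  nb <- fit$spec$likelihood == "negative_binomial"
  percoh <- fit$spec$age_effect == "per_cohort"
  npool <- nrow(fit$samples[[1L]]) * length(fit$samples)
  vapply(seq_len(npool), function(i) {
    ps <- .param_set(fit, i)
    lp <- 0
    if (dd$N > 0) {
      eta <- ps$beta_cell[dd$pcell[dd$p]] * dd$age + ps$alpha[dd$p]
      lp <- lp + if (nb) {
        sum(dcount_nb(dd$y, exp(eta), ps$noise, log = TRUE))
      } else {
        sum(stats::dnorm(dd$y, eta, sqrt(ps$noise), log = TRUE))
      }
    }
    if (dd$J > 0) {
      lp <- lp + sum(stats::dnorm(ps$alpha, ps$mu[dd$pcell],
                                  sqrt(ps$sigma2[dd$pcell]), log = TRUE))
    }
    if (is.null(fit$fixed$mu)) {
      mu_sd <- if (fit$relaxed == "mu") 100 else sqrt(pr$mu_var)
      mu_m <- if (fit$relaxed == "mu") 0 else pr$mu_mean
      lp <- lp + sum(stats::dnorm(ps$mu, mu_m, mu_sd, log = TRUE))
    }
    if (is.null(fit$fixed$sigma2)) {
      lp <- lp + if (fit$relaxed == "sigma") {
        # uniform prior on sigma: density in sigma2 gains the Jacobian term
        sum(-log(2 * sqrt(ps$sigma2)))
      } else {
        sum(.dinvgamma_log(ps$sigma2, pr$sigma2_shape, pr$sigma2_scale))
      }
    }
    if (percoh) {
      lp <- lp + sum(stats::dnorm(ps$beta_cell[!duplicated(dd$cells$cohort)],
                                  ps$beta_global, sqrt(ps$sigma2_beta), log = TRUE)) +
        stats::dnorm(ps$beta_global, pr$beta_global_mean, pr$beta_global_sd, log = TRUE) +
        .dinvgamma_log(ps$sigma2_beta, pr$sigma2_beta_shape, pr$sigma2_beta_scale)
    } else if (is.null(fit$fixed$beta_age)) {
      bsd <- if (fit$relaxed == "beta_age") 100 else pr$beta_sd
      lp <- lp + stats::dnorm(ps$beta_cell[1L], pr$beta_mean, bsd, log = TRUE)
    }
    if (!nb && is.null(fit$fixed$tau2)) {
      lp <- lp + .dinvgamma_log(ps$noise, pr$tau2_shape, pr$tau2_scale)
    }
    # omega's U(0,1) prior on omega^-1 (or the relaxed uniform on omega)
    # contributes a constant in the sampled parameterization
    lp
  }, numeric(1))
}

#' The highest-posterior-density draw
#'
#' Returns the single stored draw that maximizes the unnormalized log
#' posterior, as a parameter set ready for simulation (used as the point
#' estimator for posterior predictive checks; the posteriors of these
#' models are unimodal, so the maximizing draw is a meaningful point
#' summary).
#'
#' @param fit A `"posterior_draws"` object (with stored parent effects).
#' @return A list with `beta_cell`, `mu`, `sigma2`, `noise`
#'   (`tau2` or `omega`), `alpha`, and the pooled index of the draw.
#' @export
map_draw <- function(fit) {
  lp <- log_posterior(fit)
  i <- which.max(lp)
  out <- .param_set(fit, i)
  out$index <- i
  out$log_posterior <- lp[i]
  out
}
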