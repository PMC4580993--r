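# Posterior predictive checks: compare summary statistics of the observed
# counts with replicate datasets simulated from the fitted model, starting
# from the top of the hierarchy.

#' Sample skewness (third standardized moment)
#'
#' Measures the asymmetry of the count distribution; used as one of the
#' posterior-predictive summary statistics.
#'
#' @param x Numeric vector.
#' @return The sample skewness `m3 / m2^{3/2}`.
#' @export
sample_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# simulate one replicate dataset from a parameter set, starting from the
# highest level of the hierarchy: new parent effects from N(mu, sigma2),
# then counts from the likelihood (as the model defines it: the normal
# model is unbounded below, which is exactly what the minimum statistic
# is designed to expose)
.simulate_replicate <- function(ps, dd, likelihood) {
  alpha <- stats::rnorm(dd$J, ps$mu[dd$pcell], sqrt(ps$sigma2[dd$pcell]))
  eta <- ps$beta_cell[dd$pcell[dd$p]] * dd$age + alpha[dd$p]
  if (likelihood == "normal") {
    stats::rnorm(dd$N, eta, sqrt(ps$noise))
  } else if (ps$noise == 1) {
    stats::rpois(dd$N, exp(eta))
  } else {
    m <- exp(eta)
    stats::rnbinom(dd$N, size = m / (ps$noise - 1), prob = 1 / ps$noise)
  }
}

#' Posterior predictive check
#'
#' Simulates `n_replicates` datasets of the same size and design as the
#' observed data from the fitted model -- either all from the single
#' highest-posterior-density draw (`mode = "map_draw"`) or each from a
#' different draw of the joint posterior (`mode = "posterior_draws"`) --
#' re-drawing the parent effects from their hyperdistribution each time,
#' and compares the observed median, minimum and skewness of the counts
#' with their replicate distributions, together with per-quantile
#' envelopes of the empirical cumulative distribution function.
#'
#' @param fit A `"posterior_draws"` object with stored parent effects.
#' @param n_replicates Number of replicate datasets; default 1000.
#' @param mode `"map_draw"` (default) or `"posterior_draws"`.
#' @param seed Integer seed for the replicate simulations.
#' @param probs Quantile grid for the ECDF envelopes.
#' @return An object of class `"ppc_result"`: `observed_stats`,
#'   `replicate_stats` (one row per replicate), `ecdf_envelopes`
#'   (per-quantile min/max across replicates), `tail_probabilities`
#'   (fraction of replicates with statistic >= observed), and `mode`.
#' @export
posterior_predictive_check <- function(fit, n_replicates = 1000,
                                       mode = c("map_draw", "posterior_draws"),
                                       seed = 1,
                                       probs = seq(0.01, 0.99, by = 0.01)) {
  mode <- match.arg(mode)
  dd <- fit$data
  if (dd$N == 0L) stop("the fit holds no observed data to check against", call. = FALSE)
  y <- dd$y
  observed <- c(median = stats::median(y), min = min(y),
                skewness = sample_skewness(y))
  npool <- nrow(fit$samples[[1L]]) * length(fit$samples)
  set.seed(as.integer(seed))
  if (mode == "map_draw") {
    ps0 <- map_draw(fit)
    idx <- rep(NA_integer_, n_replicates)
  } else {
    idx <- if (npool >= n_replicates) {
      sample(npool, n_replicates)              # distinct joint-posterior draws
    } else {
      sample(npool, n_replicates, replace = TRUE)
    }
  }
  stats_mat <- matrix(NA_real_, n_replicates, 3,
                      dimnames = list(NULL, c("median", "min", "skewness")))
  qmat <- matrix(NA_real_, n_replicates, length(probs))
  for (r in seq_len(n_replicates)) {
    ps <- if (mode == "map_draw") ps0 else .param_set(fit, idx[r])
    yr <- .simulate_replicate(ps, dd, fit$spec$likelihood)
    stats_mat[r, ] <- c(stats::median(yr), min(yr), sample_skewness(yr))
    qmat[r, ] <- stats::quantile(yr, probs, names = FALSE)
  }
  structure(
    list(observed_stats = observed,
         replicate_stats = as.data.frame(stats_mat),
         ecdf_envelopes = data.frame(prob = probs,
                                     lower = apply(qmat, 2, min),
                                     upper = apply(qmat, 2, max)),
         tail_probabilities = vapply(colnames(stats_mat), function(s) {
           mean(stats_mat[, s] >= observed[[s]])
         }, numeric(1)),
         mode = mode, n_replicates = n_replicates),
    class = "ppc_result"
  )
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("posterior predictive check (%s, %d replicates)\n",
              x$mode, x$n_replicates))
  for (s in names(x$observed_stats)) {
    cat(sprintf("  %-9s observed %8.3f | replicates %8.3f (%.3f, %.3f) | Pr(rep >= obs) = %.3f\n",
                s, x$observed_stats[[s]], mean(x$replicate_stats[[s]]),
                stats::quantile(x$replicate_stats[[s]], 0.025),
                stats::quantile(x$replicate_stats[[s]], 0.975),
                x$tail_probabilities[[s]]))
  }
  invisible(x)
}
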