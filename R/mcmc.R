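# MCMC fitting of the hierarchical models. The sampling engine is JAGS
# (via rjags); model graphs are generated here from the model_spec. Ages
# are centred internally (an exact reparameterization: the prior mean of
# the cell means is shifted by beta * mean(age), leaving the joint
# posterior unchanged) to decorrelate the age effect from the parent
# effects; all stored draws are transformed back to the original
# parameterization.

#' MCMC settings
#'
#' Defaults follow the fitting protocol used throughout: four chains of
#' 10,000 draws each with the first half discarded as burn-in; if the
#' split R-hat of any parameter exceeds 1.05, the chains are extended by
#' another `n_draws` (and half of the total is then discarded), up to
#' `max_extensions` times.
#'
#' @param n_chains Number of chains; default 4.
#' @param n_draws Draws per chain per round; default 10000.
#' @param seed Integer seed; all chain RNGs derive from it.
#' @param n_adapt JAGS adaptation iterations (not counted as draws).
#' @param rhat_threshold Convergence threshold on split R-hat; default 1.05.
#' @param max_extensions Maximum number of extension rounds; default 3.
#' @param thin Optional thinning interval (default 1, i.e. off; the
#'   credible intervals are essentially unchanged by thinning).
#' @param on_nonconvergence `"error"` (default) to fail with an R-hat
#'   report when the threshold is still exceeded after all extensions,
#'   or `"warn"` to return the draws anyway.
#' @return A list of settings for [fit_model()].
#' @export
mcmc_control <- function(n_chains = 4, n_draws = 10000, seed = 1,
                         n_adapt = 500, rhat_threshold = 1.05,
                         max_extensions = 3, thin = 1,
                         on_nonconvergence = c("error", "warn")) {
  list(n_chains = as.integer(n_chains), n_draws = as.integer(n_draws),
       seed = as.integer(seed), n_adapt = as.integer(n_adapt),
       rhat_threshold = rhat_threshold,
       max_extensions = as.integer(max_extensions), thin = as.integer(thin),
       on_nonconvergence = match.arg(on_nonconvergence))
}

# ---- model-graph assembly ---------------------------------------------------

# Build the JAGS model string for a spec, a set of fixed parameters and an
# optionally relaxed ("uninformative") prior on one parameter.
.jags_model_string <- function(spec, fixed, relaxed, N, J) {
  nb <- spec$likelihood == "negative_binomial"
  percoh <- spec$age_effect == "per_cohort"
  bterm <- if (percoh) "bc[co[i]]" else "b"
  bcell <- if (percoh) "bc[cc[k]]" else "b"
  pois <- nb && !is.null(fixed$omega) && fixed$omega == 1

  lik <- if (N == 0) "" else if (!nb) {
    sprintf("  for (i in 1:N) {
    y[i] ~ dnorm(%s * (age[i] - abar) + a[p[i]], invtau2)
  }\n", bterm)
  } else if (pois) {
    sprintf("  for (i in 1:N) {
    y[i] ~ dpois(exp(%s * (age[i] - abar) + a[p[i]]))
  }\n", bterm)
  } else {
    sprintf("  for (i in 1:N) {
    y[i] ~ dnegbin(pinv, exp(%s * (age[i] - abar) + a[p[i]]) * pinv / (1 - pinv))
  }\n", bterm)
  }

  alpha <- if (J == 0) "" else
    "  for (j in 1:J) {
    a[j] ~ dnorm(mu[pc[j]], invs2[pc[j]])
  }\n"

  mu_line <- if (!is.null(fixed$mu)) {
    sprintf("    mu[k] <- mu_fix[k] + %s * abar\n", bcell)
  } else if (relaxed == "mu") {
    sprintf("    mu[k] ~ dnorm(%s * abar, 1.0E-4)\n", bcell)
  } else {
    sprintf("    mu[k] ~ dnorm(mu0 + %s * abar, muprec)\n", bcell)
  }
  sig_line <- if (!is.null(fixed$sigma2)) {
    ""  # invs2 supplied as data
  } else if (relaxed == "sigma") {
    "    sig[k] ~ dunif(0, 100)\n    invs2[k] <- pow(sig[k], -2)\n"
  } else {
    "    invs2[k] ~ dgamma(s2shape, s2rate)\n"
  }
  cells <- sprintf("  for (k in 1:K) {\n%s%s  }\n", mu_line, sig_line)

  beta <- if (!is.null(fixed$beta_age)) {
    ""  # b supplied as data
  } else if (percoh) {
    paste0("  for (c in 1:C) {\n    bc[c] ~ dnorm(bg, invs2b)\n  }\n",
           "  bg ~ dnorm(bgmean, bgprec)\n",
           "  invs2b ~ dgamma(s2bshape, s2brate)\n")
  } else if (relaxed == "beta_age") {
    "  b ~ dnorm(0, 1.0E-4)\n"
  } else {
    "  b ~ dnorm(bmean, bprec)\n"
  }

  noise <- if (!nb) {
    if (!is.null(fixed$tau2)) "" else "  invtau2 ~ dgamma(tshape, trate)\n"
  } else if (pois || !is.null(fixed$omega)) {
    ""  # pinv supplied as data (or Poisson limit)
  } else if (relaxed == "omega") {
    "  omegarel ~ dunif(1, 1000)\n  pinv <- 1 / omegarel\n"
  } else {
    "  pinv ~ dunif(0, 1)\n"
  }

  paste0("model {\n", lik, alpha, cells, beta, noise, "}\n")
}

# assemble the data list for JAGS
.jags_data <- function(spec, priors, fixed, relaxed, dd) {
  nb <- spec$likelihood == "negative_binomial"
  percoh <- spec$age_effect == "per_cohort"
  pois <- nb && !is.null(fixed$omega) && fixed$omega == 1
  dat <- list(K = dd$K, abar = dd$abar)
  if (dd$N > 0) {
    dat$y <- dd$y; dat$age <- dd$age; dat$p <- dd$p; dat$N <- dd$N
    if (percoh) dat$co <- dd$co
  }
  if (dd$J > 0) { dat$J <- dd$J; dat$pc <- dd$pcell }
  if (percoh) dat$cc <- dd$cellcoh
  if (!is.null(fixed$mu)) {
    dat$mu_fix <- rep_len(fixed$mu, dd$K)
  } else if (relaxed != "mu") {
    dat$mu0 <- priors$mu_mean; dat$muprec <- 1 / priors$mu_var
  }
  if (!is.null(fixed$sigma2)) {
    if (any(fixed$sigma2 <= 0)) stop("fixed sigma2 must be > 0", call. = FALSE)
    dat$invs2 <- 1 / rep_len(fixed$sigma2, dd$K)
  } else if (relaxed != "sigma") {
    dat$s2shape <- priors$sigma2_shape; dat$s2rate <- priors$sigma2_scale
  }
  if (!is.null(fixed$beta_age)) {
    if (percoh) stop("cannot fix beta_age in a per-cohort age-effect model", call. = FALSE)
    dat$b <- fixed$beta_age
  } else if (percoh) {
    dat$C <- dd$C
    dat$bgmean <- priors$beta_global_mean
    dat$bgprec <- 1 / priors$beta_global_sd^2
    dat$s2bshape <- priors$sigma2_beta_shape
    dat$s2brate <- priors$sigma2_beta_scale
  } else if (relaxed != "beta_age") {
    dat$bmean <- priors$beta_mean; dat$bprec <- 1 / priors$beta_sd^2
  }
  if (!nb) {
    if (!is.null(fixed$tau2)) {
      dat$invtau2 <- 1 / fixed$tau2
    } else {
      dat$tshape <- priors$tau2_shape; dat$trate <- priors$tau2_scale
    }
  } else if (!pois && !is.null(fixed$omega)) {
    dat$pinv <- 1 / fixed$omega
  }
  dat
}

# data-informed, jittered per-chain initial values
.jags_inits <- function(spec, priors, fixed, relaxed, dd, seed, chain) {
  nb <- spec$likelihood == "negative_binomial"
  percoh <- spec$age_effect == "per_cohort"
  pois <- nb && !is.null(fixed$omega) && fixed$omega == 1
  set.seed((seed * 97 + chain * 1009) %% 2147483563)
  ini <- list(.RNG.name = "base::Mersenne-Twister",
              .RNG.seed = (seed * 1000 + chain) %% 2147483563)
  bsd <- if (nb) 0.005 else 0.1
  if (is.null(fixed$beta_age)) {
    if (percoh) {
      ini$bc <- stats::rnorm(dd$C, 0, bsd)
      ini$bg <- stats::rnorm(1, 0, bsd)
    } else {
      ini$b <- stats::rnorm(1, 0, bsd)
    }
  }
  # cell-mean inits from the data (internal, age-centred parameterization)
  if (is.null(fixed$mu)) {
    cm <- if (dd$N > 0) {
      vapply(seq_len(dd$K), function(k) {
        yk <- dd$y[dd$pcell[dd$p] == k]
        if (!length(yk)) return(priors$mu_mean)
        if (nb) log(pmax(mean(yk), 0.5)) else mean(yk)
      }, numeric(1))
    } else rep(priors$mu_mean, dd$K)
    ini$mu <- cm + stats::rnorm(dd$K, 0, 0.2)
  }
  if (dd$J > 0) {
    pm <- vapply(seq_len(dd$J), function(j) mean(dd$y[dd$p == j]), numeric(1))
    ini$a <- (if (nb) log(pmax(pm, 0.5)) else pm) + stats::rnorm(dd$J, 0, 0.1)
  }
  if (is.null(fixed$sigma2)) {
    s2m <- priors$sigma2_scale / max(priors$sigma2_shape - 1, 0.5)
    if (relaxed == "sigma") {
      ini$sig <- sqrt(s2m) * exp(stats::rnorm(dd$K, 0, 0.2))
    } else {
      ini$invs2 <- (1 / s2m) * exp(stats::rnorm(dd$K, 0, 0.2))
    }
  }
  if (!nb && is.null(fixed$tau2)) {
    tv <- if (dd$N > 1) stats::var(dd$y) else priors$tau2_scale / (priors$tau2_shape - 1)
    ini$invtau2 <- (1 / max(tv, 0.5)) * exp(stats::rnorm(1, 0, 0.2))
  }
  if (nb && !pois && is.null(fixed$omega)) {
    if (relaxed == "omega") {
      ini$omegarel <- stats::runif(1, 1.3, 3)
    } else {
      ini$pinv <- stats::runif(1, 0.35, 0.8)
    }
  }
  ini
}

# ---- split R-hat ------------------------------------------------------------

#' Split R-hat (potential scale reduction) for one parameter
#'
#' Each chain is split in half and the classic between/within-chain
#' variance ratio is computed over the resulting sequences; values near 1
#' indicate convergence.
#'
#' @param mat Numeric matrix of draws, iterations by chains.
#' @return The split R-hat statistic (scalar).
#' @export
split_rhat <- function(mat) {
  n <- nrow(mat)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  pieces <- do.call(cbind, lapply(seq_len(ncol(mat)), function(ch) {
    cbind(mat[seq_len(half), ch], mat[(n - half + 1L):n, ch])
  }))
  m <- ncol(pieces); nn <- nrow(pieces)
  w <- mean(apply(pieces, 2, stats::var))
  if (!is.finite(w) || w == 0) return(1)
  b <- nn * stats::var(colMeans(pieces))
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

# ---- the fit ---------------------------------------------------------------

#' Fit a Bayesian hierarchical crossover-count model
#'
#' Fits the model described by `spec` with the priors from
#' [build_priors()] by MCMC: `n_chains` chains are run for `n_draws`
#' draws each, the first half of every chain is discarded as burn-in, and
#' split R-hat is computed for every stored parameter. If any R-hat
#' exceeds the threshold (1.05), the chains are extended by a further
#' `n_draws` (half of the enlarged chains is then discarded) and
#' convergence re-checked, up to `max_extensions` rounds, after which a
#' non-converged fit raises an error carrying the R-hat report.
#'
#' By default the meiosis table is first restricted to the stratum the
#' model is defined on: the requested parent sex; fully informative
#' meioses (configurations 2 and 6) for the cohort-level models, or all
#' configurations for the configuration-stratified ones; parents with at
#' least two meioses (a single child cannot inform the parent effect);
#' and cohorts (or cohort-by-configuration cells) with at least
#' `min_meioses` meioses.
#'
#' Stored parameters use the original (uncentred) parameterization:
#' `beta_age` (or `beta_age[<cohort>]`, `beta_age_global`, `sigma2_beta`),
#' `mu[<cell>]` and `sigma2[<cell>]` for each hierarchy cell, `tau2` or
#' `omega`, and `alpha[<parent>]` when `monitor_alpha` is `TRUE`.
#'
#' @param meioses Meiosis table.
#' @param spec A [model_spec()].
#' @param priors A `"prior_set"`; defaults to `build_priors(meioses, spec)`.
#' @param mcmc Settings from [mcmc_control()].
#' @param fixed Named list to hold parameters fixed instead of sampling
#'   them: any of `beta_age`, `mu`, `sigma2`, `tau2`, `omega`
#'   (`omega = 1` switches the likelihood to its Poisson limit). Used for
#'   degenerate checks and oracle comparisons.
#' @param relaxed Replace one prior by a deliberately uninformative
#'   alternative: `"none"` (default), `"beta_age"` (N(0, 100^2)), `"mu"`
#'   (N(0, 100^2)), `"sigma"` (uniform on the cell standard deviations),
#'   or `"omega"` (uniform on omega itself).
#' @param monitor_alpha Store the per-parent effects (needed for
#'   [log_posterior()] and the highest-posterior-density draw).
#' @param subset Apply the stratum subsetting described above.
#' @param min_meioses Exclusion threshold used when subsetting.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `"posterior_draws"`.
#' @export
fit_model <- function(meioses, spec, priors = NULL, mcmc = mcmc_control(),
                      fixed = list(), relaxed = c("none", "beta_age", "mu",
                                                  "sigma", "omega"),
                      monitor_alpha = TRUE, subset = TRUE, min_meioses = 20,
                      quiet = TRUE) {
  relaxed <- match.arg(relaxed)
  if (!inherits(spec, "model_spec")) stop("`spec` must be a model_spec", call. = FALSE)
  if (is.null(priors)) priors <- build_priors(meioses, spec)
  m <- if (subset) .model_subset(meioses, spec, min_meioses = min_meioses) else meioses
  dd <- .prep_model_data(m, spec)
  nb <- spec$likelihood == "negative_binomial"
  if (nb && dd$N > 0 && any(dd$y != round(dd$y))) {
    stop("negative-binomial models require integer counts", call. = FALSE)
  }

  mstr <- .jags_model_string(spec, fixed, relaxed, dd$N, dd$J)
  dat <- .jags_data(spec, priors, fixed, relaxed, dd)
  inits <- lapply(seq_len(mcmc$n_chains), function(ch) {
    .jags_inits(spec, priors, fixed, relaxed, dd, mcmc$seed, ch)
  })
  monitors <- .jags_monitors(spec, fixed, relaxed, dd, monitor_alpha)

  jm <- rjags::jags.model(textConnection(mstr), data = dat, inits = inits,
                          n.chains = mcmc$n_chains, n.adapt = mcmc$n_adapt,
                          quiet = quiet)
  raw <- NULL  # per-chain matrices, all rounds concatenated
  rounds <- 0L
  repeat {
    sm <- rjags::coda.samples(jm, monitors, n.iter = mcmc$n_draws,
                              thin = mcmc$thin)
    add <- lapply(sm, as.matrix)
    raw <- if (is.null(raw)) add else Map(rbind, raw, add)
    kept <- lapply(raw, function(x) {
      x[(floor(nrow(x) / 2) + 1L):nrow(x), , drop = FALSE]
    })
    nat <- .natural_scale(kept, spec, fixed, dd)
    rh <- vapply(colnames(nat[[1L]]), function(pn) {
      split_rhat(vapply(nat, function(ch) ch[, pn], numeric(nrow(nat[[1L]]))))
    }, numeric(1))
    rounds <- rounds + 1L
    if (all(rh <= mcmc$rhat_threshold, na.rm = TRUE) ||
        rounds > mcmc$max_extensions) break
  }
  if (!all(rh <= mcmc$rhat_threshold, na.rm = TRUE)) {
    bad <- sort(rh[rh > mcmc$rhat_threshold], decreasing = TRUE)
    msg <- sprintf("MCMC did not converge after %d extension(s); worst split R-hat: %s",
                   rounds - 1L,
                   paste(sprintf("%s = %.3f", names(bad)[seq_len(min(5, length(bad)))],
                                 bad[seq_len(min(5, length(bad)))]), collapse = ", "))
    if (mcmc$on_nonconvergence == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }

  samples <- coda::mcmc.list(lapply(nat, function(x) {
    coda::mcmc(x, start = 1, thin = 1)
  }))
  structure(
    list(samples = samples, rhat = rh, spec = spec, priors = priors,
         mcmc = c(mcmc, list(total_draws_per_chain = nrow(raw[[1L]]),
                             extensions_used = rounds - 1L)),
         data = dd, fixed = fixed, relaxed = relaxed,
         monitor_alpha = monitor_alpha),
    class = "posterior_draws"
  )
}

# index the meiosis table into the model frame used by the sampler
.prep_model_data <- function(m, spec) {
  star <- spec$hierarchy_level == "cohort_by_configuration"
  if (nrow(m) == 0L) {
    return(list(N = 0L, J = 0L, K = 1L, C = 1L, y = numeric(0), age = numeric(0),
                p = integer(0), co = integer(0), pcell = integer(0),
                cellcoh = 1L, abar = 0,
                parent_ids = character(0),
                cells = data.frame(cell = 1L, cohort = "none",
                                   configuration = NA_integer_,
                                   label = "none", stringsAsFactors = FALSE),
                cohorts = "none", meioses = m))
  }
  cohorts <- sort(unique(m$cohort))
  if (star) {
    cell_key <- paste(m$cohort, m$configuration, sep = ":")
  } else {
    cell_key <- m$cohort
  }
  cell_levels <- sort(unique(cell_key))
  cell_of_row <- match(cell_key, cell_levels)
  parents <- unique(m$parent_id)
  p <- match(m$parent_id, parents)
  pcell <- cell_of_row[match(parents, m$parent_id)]
  cells <- data.frame(cell = seq_along(cell_levels), label = cell_levels,
                      stringsAsFactors = FALSE)
  if (star) {
    parts <- strsplit(cell_levels, ":", fixed = TRUE)
    cells$cohort <- vapply(parts, `[`, character(1), 1L)
    cells$configuration <- as.integer(vapply(parts, `[`, character(1), 2L))
  } else {
    cells$cohort <- cell_levels
    cells$configuration <- NA_integer_
  }
  list(N = nrow(m), J = length(parents), K = length(cell_levels),
       C = length(cohorts),
       y = m$n_crossovers, age = m$parent_age_years,
       p = p, co = match(m$cohort, cohorts), pcell = pcell,
       cellcoh = match(cells$cohort, cohorts),
       abar = mean(m$parent_age_years),
       parent_ids = parents, cells = cells, cohorts = cohorts, meioses = m)
}

.jags_monitors <- function(spec, fixed, relaxed, dd, monitor_alpha) {
  nb <- spec$likelihood == "negative_binomial"
  percoh <- spec$age_effect == "per_cohort"
  pois <- nb && !is.null(fixed$omega) && fixed$omega == 1
  mon <- character(0)
  if (is.null(fixed$beta_age)) {
    mon <- c(mon, if (percoh) c("bc", "bg", "invs2b") else "b")
  }
  if (is.null(fixed$mu)) mon <- c(mon, "mu")
  if (is.null(fixed$sigma2)) mon <- c(mon, "invs2")
  if (!nb) {
    if (is.null(fixed$tau2)) mon <- c(mon, "invtau2")
  } else if (!pois && is.null(fixed$omega)) {
    mon <- c(mon, "pinv")
  }
  if (monitor_alpha && dd$J > 0) mon <- c(mon, "a")
  mon
}

# pull the columns of a (possibly length-1) JAGS vector node; JAGS names a
# length-1 vector "x", not "x[1]"
.node_cols <- function(x, base, idx) {
  nms <- sprintf("%s[%d]", base, idx)
  if (!all(nms %in% colnames(x))) {
    if (length(idx) == 1L && base %in% colnames(x)) nms <- base
    else stop(sprintf("monitored node '%s' not found in the samples", base),
              call. = FALSE)
  }
  x[, nms, drop = FALSE]
}

# transform raw (internal-parameterization) chain matrices to the natural
# scale with readable parameter names
.natural_scale <- function(kept, spec, fixed, dd) {
  nb <- spec$likelihood == "negative_binomial"
  percoh <- spec$age_effect == "per_cohort"
  pois <- nb && !is.null(fixed$omega) && fixed$omega == 1
  lapply(kept, function(x) {
    cols <- colnames(x)
    out <- list()
    if (percoh) {
      bmat <- .node_cols(x, "bc", seq_len(dd$C))
      colnames(bmat) <- sprintf("beta_age[%s]", dd$cohorts)
      out$bc <- bmat
      out$bg <- matrix(x[, "bg"], ncol = 1,
                       dimnames = list(NULL, "beta_age_global"))
      out$s2b <- matrix(1 / x[, "invs2b"], ncol = 1,
                        dimnames = list(NULL, "sigma2_beta"))
    } else if (is.null(fixed$beta_age)) {
      out$b <- matrix(x[, "b"], ncol = 1, dimnames = list(NULL, "beta_age"))
    }
    # per-draw age-effect value applying to each cell / parent
    bcell <- if (percoh) {
      .node_cols(x, "bc", seq_len(dd$C))[, dd$cellcoh, drop = FALSE]
    } else if (is.null(fixed$beta_age)) {
      matrix(x[, "b"], nrow = nrow(x), ncol = dd$K)
    } else {
      matrix(fixed$beta_age, nrow = nrow(x), ncol = dd$K)
    }
    if (is.null(fixed$mu)) {
      mu <- .node_cols(x, "mu", seq_len(dd$K)) - bcell * dd$abar
      colnames(mu) <- sprintf("mu[%s]", dd$cells$label)
      out$mu <- mu
    }
    if (is.null(fixed$sigma2)) {
      s2 <- 1 / .node_cols(x, "invs2", seq_len(dd$K))
      colnames(s2) <- sprintf("sigma2[%s]", dd$cells$label)
      out$s2 <- s2
    }
    if (!nb) {
      if (is.null(fixed$tau2)) {
        out$tau2 <- matrix(1 / x[, "invtau2"], ncol = 1,
                           dimnames = list(NULL, "tau2"))
      }
    } else if (!pois && is.null(fixed$omega)) {
      out$omega <- matrix(1 / x[, "pinv"], ncol = 1,
                          dimnames = list(NULL, "omega"))
    }
    if (dd$J > 0 && ("a[1]" %in% cols || (dd$J == 1L && "a" %in% cols))) {
      bpar <- if (percoh) {
        .node_cols(x, "bc", seq_len(dd$C))[, dd$cellcoh[dd$pcell], drop = FALSE]
      } else if (is.null(fixed$beta_age)) {
        matrix(x[, "b"], nrow = nrow(x), ncol = dd$J)
      } else {
        matrix(fixed$beta_age, nrow = nrow(x), ncol = dd$J)
      }
      al <- .node_cols(x, "a", seq_len(dd$J)) - bpar * dd$abar
      colnames(al) <- sprintf("alpha[%s]", dd$parent_ids)
      out$alpha <- al
    }
    do.call(cbind, unname(out))
  })
}

#' @export
print.posterior_draws <- function(x, ...) {
  ni <- nrow(x$samples[[1L]])
  cat(sprintf("posterior_draws: model %s (%s), %d chains x %d kept draws\n",
              x$spec$model_id, if (x$spec$parent_sex == "F") "maternal" else "paternal",
              length(x$samples), ni))
  cat(sprintf("  data: %d meioses, %d parents, %d hierarchy cells\n",
              x$data$N, x$data$J, x$data$K))
  cat(sprintf("  max split R-hat: %.3f (threshold %.2f, %d extension(s) used)\n",
              max(x$rhat, na.rm = TRUE), x$mcmc$rhat_threshold,
              x$mcmc$extensions_used))
  bn <- grep("^beta_age", .parameter_names(x), value = TRUE)[1L]
  if (!is.na(bn)) {
    d <- pooled_draws(x, bn)
    cat(sprintf("  %s: median %.5g, 95%% CrI (%.5g, %.5g), Pr(>0) = %.4f\n",
                bn, stats::median(d), stats::quantile(d, 0.025),
                stats::quantile(d, 0.975), mean(d > 0)))
  }
  invisible(x)
}
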