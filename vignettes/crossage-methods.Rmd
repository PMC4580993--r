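---
title: "Modelling parental-age effects on crossover counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling parental-age effects on crossover counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

During meiosis, homologous chromosomes exchange material at crossovers.
Whether the number of crossovers a mother transmits to a child changes
with her age at the child's birth has been contested: pedigree studies
have reported per-year effects ranging from about -0.5 to +0.2
crossovers. The question matters because recombination failure
contributes to aneuploidy, whose incidence rises steeply with maternal
age. `crossage` implements a complete multi-cohort analysis of this
question for crossover counts derived from SNP-chip pedigree data: call
post-processing, exploratory mixed models with meta-analysis, Bayesian
hierarchical models, and the model-criticism and calibration machinery
needed to trust the result.

Counts are organised per *meiosis* (one parent-child pair). A parent's
crossovers can only be assigned to a particular child in favourable
pedigree shapes, summarised by six *family configurations*: at least
three children with one/both parents genotyped (configurations 1/2), two
children with one/both parents (3/4), and two children with the
grandparents on the transmitting parent's side plus one/both parents
(5/6). Configurations 2 and 6 are *fully informative*; in the others,
HMM-based callers under-call crossovers to a cohort-dependent extent.

## Call post-processing

HMM callers attach a posterior probability `P` to each candidate
crossover; only calls with `P > 0.5` (strict) are kept. Genotyping and
phasing-switch errors masquerade as two crossovers in a short interval,
so within each meiosis and chromosome, consecutive calls separated by
fewer than X SNPs are treated as one artifact and **both** are removed,
X being the cohort's mean SNP density per megabase. Removal cascades
left to right, re-evaluating separations among survivors; overlapping
intervals count as separation below X. The same engine with a window of
five informative markers reproduces the filter used by
transmission-phasing callers. Both filters are idempotent and never mix
meioses. Because a parent effect cannot be estimated from a single
child, families contribute only when at least two children are
genotyped, and cohorts (or cohort-by-configuration cells) with fewer
than 20 meioses are excluded at the level matching the model.

## Models

Let $Y_{i,j,c}$ be the crossover count for child $i$ of parent $j$ in
cohort $c$, and $\mathrm{age}_{i,j,c}$ the parent's age at that birth.

**Normal model (M1).**
$Y_{i,j,c} \sim N(\beta_{\mathrm{age}}\,\mathrm{age}_{i,j,c} + \alpha_{j,c},\ \tau^2)$,
with parent effects $\alpha_{j,c} \sim N(\mu_c, \sigma^2_c)$ and
cohort-level means and variances drawn independently from common
hyperpriors. $\beta_{\mathrm{age}}$ is additive: crossovers per year.

**Negative-binomial model (M2).** Counts are overdispersed relative to
Poisson, so the likelihood is negative binomial parameterised by its
mean $m$ and overdispersion $\omega$: shape $a = m/(\omega - 1)$,
success probability $1/\omega$, giving $E(Y) = m$ and
$\mathrm{Var}(Y) = \omega\,E(Y)$. The link is exponential,
$m = \exp(\beta_{\mathrm{age}}\,\mathrm{age} + \alpha_{j,c})$, both
because counts must stay positive and because the shape parameter must
stay positive; $\exp(\beta_{\mathrm{age}})$ is then the multiplicative
per-year factor. $\omega^{-1}$ gets a $U(0,1)$ prior, constraining
$\omega \in (1, \infty)$; the Poisson limit $\omega = 1$ is available
as a fixed value.

**Per-cohort age effects (M1.2, M2.2, M2.2\*).** The single
$\beta_{\mathrm{age}}$ is replaced by cohort effects
$\beta_{\mathrm{age},c} \sim N(\beta_{\mathrm{age,global}},
\sigma^2_\beta)$, which exposes between-cohort heterogeneity while
sharing information.

**Configuration stratification (M2\*, M2.2\*).** Partially informative
meioses are under-called, so including them would bias cohort-level
parent-effect distributions. M2\* absorbs this by drawing
$\alpha_{j,c,f} \sim N(\mu_{c,f}, \sigma^2_{c,f})$ per (cohort,
configuration $f$) cell, letting each cell have its own baseline. This
roughly doubles the usable sample (all families with two or more
children instead of only fully informative ones) and tightens the
posterior on $\beta_{\mathrm{age}}$, which the test suite verifies on
synthetic data. The age effect itself remains shared (per cohort at
most), since under-calling scales the baseline, not the age trend.

## Priors

Priors are conjugate where possible, with some parameters set by
empirical Bayes (`build_priors()`):

* $\beta_{\mathrm{age}} \sim N(0, 1)$ -- weakly informative given that
  previously reported effects span roughly (-0.5, 0.2) crossovers/year.
* $\mu_c \sim N(41, 100)$ for maternal fits under the normal
  likelihood, 41 being the typical female crossover count; under the
  exponential link the mean becomes $\log(41) \approx 3.7$. A tight
  prior here would leak into $\beta_{\mathrm{age}}$, hence the large
  variance. Paternal fits centre on the empirical mean count instead
  (log-transformed for the count models); the variance stays 100.
* $\sigma^2_{c(,f)}$ get a common inverse-gamma prior whose mean equals
  the average of the empirical variances of per-parent mean counts
  across cohorts (log scale for the count models) and whose central
  95% interval must cover all of them. The shape starts at 3 (finite
  mean and variance) and is relaxed towards 1, keeping the mean
  matched, only if coverage demands it; shape and scale are reported in
  the `prior_set` and overridable.
* $\tau^2$ (normal likelihood) is inverse gamma with mean equal to the
  empirical count variance across fully informative meioses, shape 3.
* Per-cohort-effect models add
  $\beta_{\mathrm{age,global}} \sim N(0,1)$ and an inverse-gamma prior
  on $\sigma^2_\beta$ with mean $0.1^2$ -- the scale of the spread
  among previously reported effects; configurable.

Robustness is probed by `robustness_reruns()`: the M2\* fit is repeated
with one prior at a time replaced by an uninformative alternative
($N(0, 100^2)$ on $\beta_{\mathrm{age}}$ or $\mu$, a uniform prior on
the cell standard deviations following the usual recommendation for
variance components, and a uniform prior on $\omega$ itself), reporting
$\Pr(\beta_{\mathrm{age}} > 0)$ per rerun.

## MCMC protocol and numerical choices

Models are fitted by MCMC through JAGS (Gibbs/slice sampling): four
chains of 10,000 draws by default, first half discarded as burn-in.
Convergence is assessed by split R-hat (each chain halved, between- vs
within-sequence variance) for every stored parameter; if any exceeds
1.05, the chains are extended by another round and half of the enlarged
chains discarded, up to a configurable cap, after which the fit fails
with an R-hat report. Thinning is available but off by default --
credible intervals are essentially unchanged by it. Chain RNGs and
overdispersed initial values all derive from the single `seed`, so a
fit is exactly reproducible.

Two numerical choices matter:

* **Internal age centring.** The sampler works with
  $\mathrm{age} - \overline{\mathrm{age}}$ and shifts the prior mean of
  the cell means by $\beta\,\overline{\mathrm{age}}$, an exact
  reparameterization of the same posterior. Without it, the strong
  posterior correlation between $\beta_{\mathrm{age}}$ and the baseline
  parameters makes non-gradient samplers mix too slowly. Stored draws
  are transformed back, so reported $\mu$ and $\alpha$ keep their
  original uncentred interpretation.
* **Reported scales.** Variances are sampled as precisions (or as
  $\omega^{-1}$) and stored back-transformed; the summary table reports
  $\exp(\beta_{\mathrm{age}})$ quantiles for the count models, with
  $\Pr(\beta_{\mathrm{age}} > 0)$ always on the log scale.

Effect sizes translate between scales via
`multiplicative_to_percent(rate, years)` $= 100(r^{y}-1)$ and
`multiplicative_to_additive(rate, baseline)` $= b\log r$ with a default
baseline of 38 crossovers, the value inferred from SNP-chip data.

## Model criticism and calibration

`posterior_predictive_check()` simulates replicate datasets of the
observed size and design, starting from the top of the hierarchy (new
parent effects from their hyperdistribution, then counts), either all
from the single highest-posterior-density draw or one per joint
posterior draw, and compares the observed median, minimum and sample
skewness (the third standardized moment -- the package's concrete
choice for the distribution's asymmetry) with the replicate
distributions, plus ECDF envelopes. Normal-model replicates are
simulated without a lower bound: that unboundedness is exactly the
deficiency the minimum statistic exposes on right-skewed counts. The
highest-posterior-density draw is the stored draw maximizing the
unnormalized log posterior, a meaningful point summary because these
posteriors are unimodal.

`coverage_power_assessment()` estimates the frequentist properties of
the credible intervals around the fitted posterior: the age-effect
draws are cut into equal-count bins (deciles by default, which
guarantees the minimum draw count per bin whenever the protocol's
10,000+ draws are available), full parameter sets are resampled from
each bin -- taken jointly from single draws so all parameters are
mutually consistent -- a dataset is simulated per set on the observed
design, and the model refitted. Coverage $\gamma$ is the fraction of
refits whose interval contains the simulating effect; power $\pi$ the
fraction excluding zero. Refits default to a reduced protocol
(2 chains x 2,000 draws, R-hat rule intact) to keep the procedure
desk-scale.

`prior_calibration()` is the prior-draw (simulation-based-calibration)
variant: parameters drawn from the prior, for which the coverage of a
level-$\ell$ interval must equal $\ell$ exactly up to Monte-Carlo
error. Two design choices here: (i) it supports the normal-likelihood
models only, because an age effect drawn from $N(0,1)$ under the
exponential link produces overflow-scale counts -- the count models are
calibrated through the posterior-bin procedure instead; and (ii) the
replicate counts are rounded but *not* truncated at zero, since
prior-drawn effects can push the normal mean below zero and censoring
would break the very identity being measured. With `beta_true = 0` the
same machinery measures type-I behaviour.

## The synthetic-data generator

`simulate_cohorts()` emulates the structure of a nine-cohort SNP-chip
consortium: per-cohort family counts across the six configurations
(heterogeneous cohort sizes, from a handful of families to over a
thousand meioses, under `default_cohort_specs()`), truncated-normal
maternal age distributions centred in the late twenties with
inter-birth intervals of at least one year (ages strictly increase with
birth order), a paternal age offset, parent effects drawn per (cohort,
configuration) cell, counts from either likelihood, and binomial
thinning of true counts by a per-cell detection probability -- 1 in the
fully informative configurations, 0.9 elsewhere by default -- mimicking
configuration-dependent under-calling. The default truth uses a
multiplicative age effect of 1.00213 per year and a baseline of about
38 maternal crossovers at the typical age, overdispersion 1.9, and
modest between-mother variation; true age distributions per real cohort
are not published, so the defaults are configurable, not canonical.
Normal-model counts are rounded to non-negative integers so downstream
count handling is uniform, while inference still treats them as
continuous. Randomness streams per cohort (seeded from a hash of the
cohort id) and splits per family, so adding a cohort never perturbs the
others. `simulate_call_table()` expands counts to call level and can
inject the two artifact classes the filters target -- tight double-call
pairs below the cohort's X and low-confidence calls -- recording their
coordinates so filter recovery can be scored against the truth ledger.

What the generator does **not** emulate: genotype-level error processes
(it starts at true crossovers), chromosome-specific crossover
interference, non-linear age trends, family-size/recombination
correlations, and real cohorts' age distributions. Passing tests
therefore demonstrate the correctness and calibration of the machinery
under the stated generative assumptions, not the field validity of any
particular biological estimate.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen as the smallest sizes at which the checks are statistically
sharp: moment contracts at 10,000+ meioses; parameter recovery on 5
cohorts x 4 configurations with 1,500 mothers fitted with 4 chains x
2,000 draws; prior-draw calibration and type-I behaviour with 100
refits of a 160-meiosis two-cohort design at 2 chains x 1,000 draws;
posterior predictive checks with 200-500 replicates. The full protocol
(4 x 10,000 draws, 10 bins x 100 sets) is the default of the exported
functions.

## Known limitations

* The sampling engine is Gibbs/slice-based; heavily imbalanced designs
  mix more slowly than they would under gradient-based samplers, which
  the centring reparameterization and the extension rule mitigate but
  do not eliminate.
* Detection thinning is part of the generator but not of the
  likelihood; M2\* absorbs it through cell-specific baselines, which is
  exactly the modelling stance the stratification exists for, but a
  misspecified detection model still shifts cell means, not the age
  effect.
* `fit_lmm()` assumes a linear age trend; non-linearity must be probed
  by the binned exploratory summary (`binned_age_summary()`).
* Paternal prior centring uses the empirical mean count; there is no
  published canonical paternal value analogous to the maternal 41.
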