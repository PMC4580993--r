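# Conversions between the multiplicative (negative-binomial, log-link) and
# additive (normal-model) scales of the per-year age effect.

#' Percent increase over a number of years from a multiplicative rate
#'
#' Under the exponential link, the expected count is multiplied by
#' `rate = exp(beta_age)` each year, so over `years` years it grows by
#' `100 * (rate^years - 1)` percent. This is the transformation used to
#' report, e.g., the 10-year percent increase implied by a posterior
#' quantile of `exp(beta_age)`.
#'
#' @param rate Multiplicative per-year factor(s); positive.
#' @param years Horizon in years; default 10.
#' @return Percent increase(s).
#' @examples
#' multiplicative_to_percent(1.00213)  # ~2.15% over 10 years
#' @export
multiplicative_to_percent <- function(rate, years = 10) {
  if (any(rate <= 0)) stop("`rate` must be > 0", call. = FALSE)
  100 * (rate^years - 1)
}

#' Additive crossovers-per-year equivalent of a multiplicative rate
#'
#' A multiplicative per-year factor `rate` applied to a baseline of
#' `baseline` crossovers corresponds, for small effects, to an additive
#' change of `baseline * log(rate)` crossovers per year -- the scale on
#' which the normal model's `beta_age` lives.
#'
#' @param rate Multiplicative per-year factor(s); positive.
#' @param baseline Baseline crossover count; default 38 (the typical
#'   maternal count inferred from SNP-chip data).
#' @return Crossovers per year.
#' @examples
#' multiplicative_to_additive(1.013)  # ~0.49 crossovers/year
#' @export
multiplicative_to_additive <- function(rate, baseline = 38) {
  if (any(rate <= 0)) stop("`rate` must be > 0", call. = FALSE)
  if (any(baseline <= 0)) stop("`baseline` must be > 0", call. = FALSE)
  baseline * log(rate)
}
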