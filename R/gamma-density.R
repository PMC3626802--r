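#' Compound-gamma (gamma scale-mixture) log density
#'
#' Marginal density of an intensity y under the probe-level model
#' y | beta ~ Gamma(shape a, rate beta), beta ~ Gamma(shape c, rate d),
#' integrating the probe-effect rate beta out analytically:
#' \deqn{p(y) = \frac{\Gamma(a+c)}{\Gamma(a)\Gamma(c)}
#'              \frac{d^c \, y^{a-1}}{(y+d)^{a+c}}.}
#' This is the per-(probe, array) factor of the marginal likelihood of both
#' summarisation models (the multi-mapping exon model uses the summed
#' isoform shape for `a`; the PM-only probe-set model uses its per-array
#' shape directly).
#'
#' @param y positive intensity (vectorised).
#' @param a gamma shape of the signal (> 0, vectorised).
#' @param c_shape,d_rate shape and rate of the gamma prior on the
#'   probe-effect rate (> 0).
#' @return log density, same length as the longest argument.
#' @export
compound_gamma_logpdf <- function(y, a, c_shape, d_rate) {
  if (any(!is.finite(y) | y <= 0)) stop_value("y must be positive and finite")
  if (any(!is.finite(a) | a <= 0)) stop_value("shape a must be positive")
  if (any(!is.finite(c_shape) | c_shape <= 0)) stop_value("prior shape must be positive")
  if (any(!is.finite(d_rate) | d_rate <= 0)) stop_value("prior rate must be positive")
  lgamma(a + c_shape) - lgamma(a) - lgamma(c_shape) +
    c_shape * log(d_rate) + (a - 1) * log(y) - (a + c_shape) * log(y + d_rate)
}

# Exact moments of log(s) for s | beta ~ Ga(a, rate beta), beta ~ Ga(c, rate d):
# log s = log Ga(a,1) - log beta, the two terms independent, so
#   E[log s]  = digamma(a) - digamma(c) + log(d)
#   Var[log s] = trigamma(a) + trigamma(c)
# Returned on the natural-log scale; callers divide by log(2) for log2.
compound_gamma_log_moments <- function(a, c_shape, d_rate) {
  list(mean = digamma(a) - digamma(c_shape) + log(d_rate),
       var  = trigamma(a) + trigamma(c_shape))
}

# Gaussian summary (log2 scale) of the compound-gamma expression posterior.
log2_summary <- function(a, c_shape, d_rate) {
  mo <- compound_gamma_log_moments(a, c_shape, d_rate)
  list(mean = mo$mean / LOG2, sd = sqrt(mo$var) / LOG2)
}
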