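#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @useDynLib fireantdemog, .registration = TRUE
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Derive a child seed (< 2^31) from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 7919) %% 2147483399 + 1
}

#' Round to a number of significant figures
#'
#' @param x Numeric vector.
#' @param sig_figs Significant figures to keep (default 2, the reporting
#'   convention used throughout).
#' @return `x` rounded to `sig_figs` significant figures.
#' @export
signif_round <- function(x, sig_figs = 2) signif(x, sig_figs)

#' Weighted quantiles of a sample
#'
#' Quantiles of a weighted empirical distribution, computed on the sorted
#' sample with cumulative normalized weights (inverse-CDF definition, no
#' interpolation beyond the step function).
#'
#' @param x Numeric vector.
#' @param w Non-negative weights, same length as `x`.
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

# Gauss-Legendre nodes/weights on [a, b].
gauss_legendre <- function(k, a = 0, b = 1) {
  gl <- pracma::gaussLegendre(k, a, b)
  list(nodes = gl$x, weights = gl$w)
}
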