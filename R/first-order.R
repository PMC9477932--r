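#' First-order intensity statistics
#'
#' Moments and histogram statistics of the lesion TBR values: mean, SD,
#' skewness and kurtosis (population moment ratios; 0 for a constant
#' lesion), min, max, range, energy (sum of squares), plus entropy (log
#' base 2) and uniformity of the discretized gray-level histogram.
#'
#' @param values lesion TBR (or coefficient) values.
#' @param droi the matching [discretize()] result, for the histogram
#'   statistics.
#' @return Named numeric vector.
#' @export
first_order_features <- function(values, droi) {
  if (!inherits(droi, "discretized_roi")) stop("need a discretized_roi")
  n <- length(values)
  if (n == 0L) stop("empty ROI")
  mu <- mean(values)
  cent <- values - mu
  m2 <- mean(cent^2)
  m3 <- mean(cent^3)
  m4 <- mean(cent^4)
  skew <- if (m2 > 1e-24) m3 / m2^1.5 else 0
  kurt <- if (m2 > 1e-24) m4 / m2^2 else 0
  lev <- droi$levels[!is.na(droi$levels)]
  p <- tabulate(lev) / length(lev)
  p <- p[p > 0]
  c(fo_mean = mu,
    fo_sd = sqrt(m2),
    fo_skewness = skew,
    fo_kurtosis = kurt,
    fo_min = min(values),
    fo_max = max(values),
    fo_range = max(values) - min(values),
    fo_energy = sum(values^2),
    fo_entropy = -sum(p * log2(p)),
    fo_uniformity = sum(p^2))
}
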