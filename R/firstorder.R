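#' First-order (intensity histogram) features of an ROI
#'
#' Statistics of the raw intensity distribution inside the mask. Entropy and
#' uniformity are computed on the fixed-bin-width discretized levels (base-2
#' logarithm); everything else uses the raw intensities. Population (biased)
#' moment estimators are used for variance, skewness and kurtosis; kurtosis
#' is not excess-corrected.
#'
#' @param vol an `image_volume`.
#' @param mask an aligned nonempty `seg_mask`.
#' @param spec a [discretization_spec()] for entropy/uniformity.
#' @return named numeric vector of first-order features.
#' @export
extract_firstorder <- function(vol, mask, spec = discretization_spec()) {
  assert_aligned(vol, mask)
  x <- vol$voxels[mask$voxels]
  n <- length(x)
  if (n == 0L) stop("empty mask", call. = FALSE)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skew <- if (m2 > 1e-24) m3 / m2^1.5 else 0
  kurt <- if (m2 > 1e-24) m4 / m2^2 else NA_real_

  disc <- discretize(vol, mask, spec)
  lev <- disc$levels[disc$levels > 0L]
  p <- tabulate(lev) / length(lev)
  p <- p[p > 0]
  entropy <- -sum(p * log2(p))
  uniformity <- sum(p^2)

  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  mid <- x[x >= q[1] & x <= q[4]]

  c(mean = mu,
    median = stats::median(x),
    minimum = min(x),
    maximum = max(x),
    range = max(x) - min(x),
    variance = m2,
    standard_deviation = sqrt(m2),
    skewness = skew,
    kurtosis = kurt,
    energy = sum(x^2),
    entropy = entropy,
    uniformity = uniformity,
    percentile10 = q[1],
    percentile90 = q[4],
    interquartile_range = q[3] - q[2],
    mean_absolute_deviation = mean(abs(x - mu)),
    robust_mean_absolute_deviation = mean(abs(mid - mean(mid))),
    root_mean_squared = sqrt(mean(x^2)))
}
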