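FIRSTORDER_NAMES <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"
)

#' First-order (histogram) features
#'
#' The standard 18-feature first-order set. Entropy and Uniformity are
#' computed on discretized gray levels; all other statistics on the raw
#' intensities. Percentiles use linear interpolation. Variance, skewness and
#' kurtosis use population (1/n) moments; kurtosis is not excess-corrected.
#' Zero-variance input yields skewness and kurtosis of 0 with a degenerate
#' flag.
#'
#' @param values numeric vector of masked intensities
#' @param levels optional integer gray levels matching `values`; derived with
#'   `config` when missing
#' @param spacing voxel spacing in mm (for TotalEnergy)
#' @param config a [discretization_config()] used when `levels` is missing
#' @return named numeric vector of 18 features with a logical `degenerate`
#'   attribute
#' @export
first_order_features <- function(values, levels = NULL, spacing = c(1, 1, 1),
                                 config = discretization_config()) {
  assert_that(length(values) >= 1, "at least one voxel is required")
  if (is.null(levels)) levels <- discretize(values, config)
  n <- length(values)
  p <- tabulate(levels) / n
  p <- p[p > 0]
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  q <- unname(quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7))
  rob <- values[values >= q[1] & values <= q[5]]
  degenerate <- setNames(rep(FALSE, length(FIRSTORDER_NAMES)),
                         FIRSTORDER_NAMES)
  if (m2 <= 0) degenerate[c("Skewness", "Kurtosis")] <- TRUE
  out <- c(
    Energy = sum(values^2),
    TotalEnergy = prod(spacing) * sum(values^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(values),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(values),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
  attr(out, "degenerate") <- degenerate
  out
}
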