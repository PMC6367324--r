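#' First-order histogram features
#'
#' Computes the 15 first-order intensity features over the in-mask pixels:
#' mean, standard deviation, variance, skewness, excess kurtosis, minimum,
#' maximum, range, median, the 10/25/75/90 percentiles, intensity entropy
#' (base 2, on a `levels`-bin min-max quantized histogram) and uniformity
#' (sum of squared bin probabilities).
#'
#' Skewness and kurtosis use population central moments and are defined as 0
#' when the in-mask standard deviation is 0; a constant image has entropy 0
#' and uniformity 1.
#'
#' @param roi A [roi_image()].
#' @param levels Histogram bin count for entropy/uniformity (default 64).
#'
#' @return Named numeric vector of length 15 (names from
#'   [feature_manifest()]'s `hist_*` block).
#' @export
histogram_features <- function(roi, levels = 64L) {
  if (!inherits(roi, "roi_image")) stop_invalid("roi must be an roi_image")
  v <- mask_values(roi)
  n <- length(v)
  m <- mean(v)
  s <- stats::sd(v)
  m2 <- mean((v - m)^2)
  skew <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - m)^4) / m2^2 - 3 else 0
  qs <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  q <- quantize(roi, levels)
  p <- tabulate(q[roi$mask] + 1L, nbins = levels) / n
  p_pos <- p[p > 0]
  out <- c(
    m, s, stats::var(v), skew, kurt,
    min(v), max(v), max(v) - min(v), qs[3],
    qs[1], qs[2], qs[4], qs[5],
    -sum(p_pos * log2(p_pos)), sum(p^2)
  )
  names(out) <- hist_feature_names()
  out
}
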