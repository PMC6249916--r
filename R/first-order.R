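#' First-order (histogram) features of an ROI
#'
#' Fourteen intensity-distribution descriptors of the in-mask pixels:
#' mean, median, min, max, range, variance, standard deviation, skewness,
#' excess kurtosis, 10th and 90th percentiles, interquartile range, and the
#' histogram entropy (base 2) and uniformity computed over the `Ng`
#' quantized bins. Variance is the population form (denominator n);
#' skewness and kurtosis of a constant ROI are 0 by convention.
#'
#' @param image A [roi_image].
#' @param quantized The matching [quantize_roi] result (supplies the
#'   histogram binning for entropy and uniformity).
#' @return Named numeric vector of 14 features (names prefixed `fo_`).
#' @examples
#' img <- roi_image(matrix(1:4, 2, 2), matrix(TRUE, 2, 2))
#' first_order_features(img, quantize_roi(img, 4))
#' @export
first_order_features <- function(image, quantized) {
  stopifnot(inherits(image, "roi_image"), inherits(quantized, "quantized_roi"))
  x <- image$pixels[image$mask]
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)          # population variance
  skew <- 0
  kurt <- 0
  if (m2 > 0) {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2 - 3   # excess (Fisher)
  }
  qs <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  p <- tabulate(quantized$levels[quantized$mask], quantized$n_levels) / n
  c(fo_mean = m,
    fo_median = stats::median(x),
    fo_min = min(x),
    fo_max = max(x),
    fo_range = max(x) - min(x),
    fo_variance = m2,
    fo_sd = sqrt(m2),
    fo_skewness = skew,
    fo_kurtosis = kurt,
    fo_p10 = qs[1],
    fo_p90 = qs[4],
    fo_iqr = qs[3] - qs[2],
    fo_entropy = -sum(xlog2x(p)),
    fo_uniformity = sum(p^2))
}
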