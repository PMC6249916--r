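#' Quantize ROI intensities to discrete gray levels
#'
#' Rebins the in-mask intensities into `n_levels` equal-width bins spanning
#' the in-mask minimum to maximum. Texture matrices (co-occurrence,
#' run-length) are defined on these levels. A constant ROI maps every pixel
#' to level 1.
#'
#' @param image A [roi_image].
#' @param n_levels Number of gray levels Ng (>= 2); default 32.
#' @return An object of class `quantized_roi`: `levels` (integer matrix,
#'   values `1..Ng` inside the mask, `0` outside), `n_levels`, `bin_edges`
#'   (Ng + 1 ascending intensities) and the originating `mask`.
#' @examples
#' img <- roi_image(matrix(0:15, 4, 4), matrix(TRUE, 4, 4))
#' q <- quantize_roi(img, 4)
#' table(q$levels)
#' @export
quantize_roi <- function(image, n_levels = 32L) {
  stopifnot(inherits(image, "roi_image"))
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop_input("'n_levels' must be at least 2")
  vals <- image$pixels[image$mask]
  lo <- min(vals)
  hi <- max(vals)
  lv <- matrix(0L, nrow(image$pixels), ncol(image$pixels))
  if (hi == lo) {
    # constant ROI: single occupied level, degenerate edges
    lv[image$mask] <- 1L
    edges <- lo + seq(0, 1, length.out = n_levels + 1L)
  } else {
    w <- (hi - lo) / n_levels
    k <- pmin(floor((vals - lo) / w) + 1, n_levels)
    lv[image$mask] <- as.integer(k)
    edges <- lo + w * (0:n_levels)
  }
  structure(list(levels = lv, n_levels = n_levels, bin_edges = edges,
                 mask = image$mask),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> Ng = %d, %d in-mask pixels, %d occupied levels\n",
              x$n_levels, sum(x$mask), length(unique(x$levels[x$mask]))))
  invisible(x)
}
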