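#' Gray-level co-occurrence matrix
#'
#' Counts pairs of quantized gray levels at a fixed pixel offset, keeping
#' only pairs whose two pixels are both inside the mask, and symmetrizes
#' (each pair is counted in both orders). The result is normalized to sum
#' to 1 when at least one valid pair exists; otherwise it is flagged
#' degenerate and left all-zero.
#'
#' @param quantized A [quantize_roi] result.
#' @param offset Integer vector `c(dr, dc)`, the row/column displacement of
#'   the second pixel of each pair; must not be `c(0, 0)`.
#' @return An `Ng x Ng` matrix of class `glcm` with attributes `offset`,
#'   `n_pairs` (directed pair count) and `degenerate`.
#' @examples
#' img <- roi_image(matrix(c(1, 1, 1, 2), 2, 2), matrix(TRUE, 2, 2))
#' glcm(quantize_roi(img, 2), c(0, 1))
#' @export
glcm <- function(quantized, offset) {
  stopifnot(inherits(quantized, "quantized_roi"))
  offset <- as.integer(offset)
  if (length(offset) != 2L || all(offset == 0L)) {
    stop_input("'offset' must be a nonzero (dr, dc) pair")
  }
  lv <- quantized$levels
  ng <- quantized$n_levels
  nr <- nrow(lv)
  nc <- ncol(lv)
  dr <- offset[1]
  dc <- offset[2]
  r_lo <- max(1L, 1L - dr)
  r_hi <- min(nr, nr - dr)
  c_lo <- max(1L, 1L - dc)
  c_hi <- min(nc, nc - dc)
  if (r_lo <= r_hi && c_lo <= c_hi) {
    r1 <- r_lo:r_hi
    c1 <- c_lo:c_hi
    a <- lv[r1, c1, drop = FALSE]
    b <- lv[r1 + dr, c1 + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    a <- a[keep]
    b <- b[keep]
  } else {
    a <- b <- integer(0)
  }
  P <- matrix(0, ng, ng)
  n_pairs <- length(a)
  if (n_pairs > 0L) {
    counts <- tabulate((a - 1L) * ng + b, ng * ng)
    P[] <- counts
    P <- P + t(P)                 # symmetric: both orderings
    P <- P / sum(P)
  }
  structure(P, class = c("glcm", "matrix"), offset = offset,
            n_pairs = n_pairs, degenerate = n_pairs == 0L)
}

#' Haralick features of a co-occurrence matrix
#'
#' The 13 classical descriptors: angular second moment (energy), contrast,
#' correlation, sum-of-squares variance, inverse difference moment
#' (homogeneity), sum average, sum variance, sum entropy, entropy,
#' difference variance, difference entropy, and the two information
#' measures of correlation. Logarithms are base 2 with the convention
#' `0 * log 0 = 0`. A degenerate single-cell matrix has correlation 1 by
#' convention; the second information measure is clamped to `[0, 1]`.
#'
#' @param P A normalized (and typically symmetric) co-occurrence matrix,
#'   e.g. from [glcm()].
#' @return Named numeric vector of 13 features (names prefixed `glcm_`).
#' @examples
#' haralick_features(matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
#' @export
haralick_features <- function(P) {
  P <- unclass(as.matrix(P))
  ng <- nrow(P)
  tot <- sum(P)
  if (isTRUE(attr(P, "degenerate")) || tot == 0) {
    # no valid pair: neutral conventions keep the vector finite
    return(c(glcm_energy = 1, glcm_contrast = 0, glcm_correlation = 1,
             glcm_variance = 0, glcm_idm = 1, glcm_sum_average = 0,
             glcm_sum_variance = 0, glcm_sum_entropy = 0, glcm_entropy = 0,
             glcm_diff_variance = 0, glcm_diff_entropy = 0,
             glcm_imc1 = 0, glcm_imc2 = 0))
  }
  if (abs(tot - 1) > 1e-8) P <- P / tot
  i <- row(P)
  j <- col(P)
  px <- rowSums(P)
  py <- colSums(P)
  mx <- sum((1:ng) * px)
  my <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mx)^2 * px))
  sy <- sqrt(sum(((1:ng) - my)^2 * py))

  # p_{x+y}(k), k = 2..2Ng and p_{x-y}(k), k = 0..Ng-1
  psum <- as.vector(tapply(P, i + j, sum))
  ksum <- sort(unique(as.vector(i + j)))
  pdiff <- as.vector(tapply(P, abs(i - j), sum))
  kdiff <- sort(unique(as.vector(abs(i - j))))

  energy <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sx > 0 && sy > 0) {
    (sum(i * j * P) - mx * my) / (sx * sy)
  } else 1
  variance <- sum((i - mx)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_average <- sum(ksum * psum)
  sum_variance <- sum((ksum - sum_average)^2 * psum)
  sum_entropy <- -sum(xlog2x(psum))
  entropy <- -sum(xlog2x(P))
  diff_average <- sum(kdiff * pdiff)
  diff_variance <- sum((kdiff - diff_average)^2 * pdiff)
  diff_entropy <- -sum(xlog2x(pdiff))

  hx <- -sum(xlog2x(px))
  hy <- -sum(xlog2x(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * ifelse(pxpy > 0, log2(pxpy), 0))
  hxy2 <- -sum(xlog2x(pxpy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * log(2) * (hxy2 - entropy))))
  imc2 <- min(1, max(0, imc2))

  c(glcm_energy = energy, glcm_contrast = contrast,
    glcm_correlation = correlation, glcm_variance = variance,
    glcm_idm = idm, glcm_sum_average = sum_average,
    glcm_sum_variance = sum_variance, glcm_sum_entropy = sum_entropy,
    glcm_entropy = entropy, glcm_diff_variance = diff_variance,
    glcm_diff_entropy = diff_entropy, glcm_imc1 = imc1, glcm_imc2 = imc2)
}
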