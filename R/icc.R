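#' Intraclass correlation ICC(2,1), absolute agreement
#'
#' Two-way random-effects, single-measure, absolute-agreement intraclass
#' correlation from the standard two-way ANOVA decomposition of an
#' n-subject by k-rater table:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' where MSR, MSC and MSE are the mean squares for rows (subjects),
#' columns (raters) and residual error. Systematic rater offsets lower
#' this form (unlike the consistency form), which is what makes it an
#' absolute-agreement measure.
#'
#' @param ratings Numeric matrix, subjects in rows (n >= 2), raters in
#'   columns (k >= 2), finite values.
#' @return An object of class `icc_result`: `icc`, `components` (`MSR`,
#'   `MSC`, `MSE`), `n`, `k`, `degenerate` (`TRUE` when the table has
#'   zero total variance, in which case the ICC is defined as 1).
#' @examples
#' icc_2_1(matrix(c(1, 3, 5, 2, 4, 6), ncol = 2))$icc  # 8/9
#' @export
icc_2_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2) stop_input("need at least 2 subjects and 2 raters")
  if (any(!is.finite(ratings))) stop_input("non-finite ratings")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  if (ss_total == 0) {
    return(structure(list(icc = 1,
                          components = list(MSR = 0, MSC = 0, MSE = 0),
                          n = n, k = k, degenerate = TRUE),
                     class = "icc_result"))
  }
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = icc, components = list(MSR = msr, MSC = msc, MSE = mse),
                 n = n, k = k, degenerate = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.4f (%s)%s; n = %d subjects, k = %d raters\n",
              x$icc, classify_icc(max(-1, min(1, x$icc))),
              if (x$degenerate) " [degenerate: zero variance]" else "",
              x$n, x$k))
  invisible(x)
}

#' Classify an ICC value as reliability grade
#'
#' Below 0.40 is poor, 0.41-0.59 fair, 0.60-0.74 good and 0.75-1.00
#' excellent; the boundaries resolve as 0.40 poor, 0.60 good, 0.75
#' excellent.
#'
#' @param value ICC value(s) in `[-1, 1]`.
#' @return Character vector of `"poor"`, `"fair"`, `"good"`,
#'   `"excellent"`.
#' @examples
#' classify_icc(c(0.39, 0.6, 0.75))
#' @export
classify_icc <- function(value) {
  if (any(value < -1 | value > 1)) stop_input("ICC must lie in [-1, 1]")
  out <- rep("poor", length(value))
  out[value > 0.40] <- "fair"
  out[value >= 0.60] <- "good"
  out[value >= 0.75] <- "excellent"
  out
}

# Chebyshev dilation (r > 0) or erosion (r < 0) of a binary mask by |r|
# one-pixel steps.
morph_mask <- function(mask, r) {
  if (r == 0) return(mask)
  op <- if (r > 0) `|` else `&`
  shift1 <- function(m) {
    nr <- nrow(m)
    nc <- ncol(m)
    acc <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      sh <- matrix(r < 0, nr, nc)   # pad: FALSE for dilation, TRUE for erosion
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      sh[rs, cs] <- m[rs - dr, cs - dc]
      acc <- op(acc, sh)
    }
    acc
  }
  for (i in seq_len(abs(r))) mask <- shift1(mask)
  mask
}

# Random mask perturbation emulating a re-delineation. Membership of the
# boundary band (mask dilated/eroded by `radius`) is redrawn from a
# spatially smoothed random field, so the contour moves in contiguous
# bulges and notches - the way two freehand outlines differ - rather
# than by isolated pixel flips. `boundary_prob` is the expected fraction
# of each band side that changes.
perturb_mask <- function(mask, radius = 1L, boundary_prob = 0.2) {
  if (radius < 0 || boundary_prob < 0 || boundary_prob > 0.5) {
    stop_input("need radius >= 0 and boundary_prob in [0, 0.5]")
  }
  if (radius == 0 || boundary_prob == 0) return(mask)
  g <- smooth_field(matrix(stats::rnorm(length(mask)), nrow(mask)), 4)
  z <- stats::qnorm(1 - boundary_prob)
  band_out <- morph_mask(mask, radius) & !mask
  band_in <- mask & !morph_mask(mask, -radius)
  out <- mask
  out[band_out] <- g[band_out] > z    # contiguous outward bulges
  out[band_in] <- g[band_in] > -z     # contiguous inward notches
  out
}

#' Re-extract features under mask perturbation
#'
#' Emulates a second reader (or a second read) by re-delineating each
#' tumor mask with seeded random jitter - redrawing membership of the
#' `radius`-pixel boundary band from a spatially smoothed random field,
#' so contours differ by contiguous bulges and notches - and
#' re-extracting
#' all features. Returns the original and perturbed feature tables as
#' paired ratings for [icc_feature_table()]. Human readers are not
#' simulated; this is a reproducibility surrogate that stresses the same
#' boundary sensitivity a re-delineation does.
#'
#' @param images List of [roi_image] objects.
#' @param radius Half-width of the perturbed boundary band in pixels
#'   (>= 0; 0 disables the perturbation).
#' @param boundary_prob Expected fraction of each band side whose
#'   membership changes, in `[0, 0.5]`.
#' @param catalog Feature catalog.
#' @param seed Seed for the perturbations.
#' @return List with `original` and `perturbed` feature data frames
#'   (subjects whose perturbed mask became empty are dropped with a
#'   warning) and `dropped` (ids).
#' @export
perturbed_rereads <- function(images, radius = 1L, boundary_prob = 0.2,
                              catalog = feature_catalog(), seed = 1L) {
  orig <- extract_feature_table(images, catalog)
  pert <- with_seed(seed, {
    lapply(images, function(im) {
      mk <- perturb_mask(im$mask, radius, boundary_prob)
      if (!any(mk)) return(NULL)
      extract_features(roi_image(im$pixels, mk, id = im$id), catalog)
    })
  })
  ok <- !vapply(pert, is.null, logical(1))
  dropped <- vapply(images[!ok], function(im) im$id, character(1))
  if (length(dropped)) {
    warning("perturbation emptied mask(s); dropped: ",
            paste(dropped, collapse = ", "))
  }
  pmat <- do.call(rbind, pert[ok])
  perturbed <- cbind(data.frame(patient_id = orig$patient_id[ok],
                                stringsAsFactors = FALSE),
                     as.data.frame(pmat))
  list(original = orig[ok, , drop = FALSE], perturbed = perturbed,
       dropped = dropped)
}

#' Per-feature ICC between two feature tables
#'
#' Pairs the feature columns of two tables (same subjects, e.g. two
#' readers or two reads) and computes ICC(2,1) per feature, with the
#' reliability grade. Features with zero between-subject variance are
#' flagged degenerate rather than silently scored.
#'
#' @param a,b Feature data frames sharing a `patient_id` column and the
#'   same feature columns.
#' @return Data frame with `feature`, `icc`, `grade`, `degenerate`.
#' @export
icc_feature_table <- function(a, b) {
  ids <- intersect(a$patient_id, b$patient_id)
  a <- a[match(ids, a$patient_id), , drop = FALSE]
  b <- b[match(ids, b$patient_id), , drop = FALSE]
  feats <- setdiff(intersect(names(a), names(b)), "patient_id")
  rows <- lapply(feats, function(f) {
    tab <- cbind(a[[f]], b[[f]])
    r <- icc_2_1(tab)
    deg <- r$degenerate || stats::var(rowMeans(tab)) == 0
    data.frame(feature = f, icc = r$icc,
               grade = classify_icc(max(-1, min(1, r$icc))),
               degenerate = deg)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
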