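#' The default 110-feature texture catalog
#'
#' Enumerates the features [extract_features()] computes: 14 first-order
#' descriptors, 13 Haralick co-occurrence features at each of the four
#' distance-1 offsets (0,1), (1,0), (1,1), (1,-1) reported separately
#' (52), and 11 run-length features along the same four directions (44) —
#' 110 named features in total. The catalog doubles as extraction metadata:
#' it records the family, offset/direction and gray-level count of every
#' feature and is written alongside feature tables.
#'
#' @param n_levels Gray-level count Ng used for quantization (default 32).
#' @return A data frame of class `feature_catalog` with columns `name`,
#'   `family`, `offset_dr`, `offset_dc`, `n_levels`.
#' @examples
#' nrow(feature_catalog())  # 110
#' @export
feature_catalog <- function(n_levels = 32L) {
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  off_tag <- function(o) paste0(o[1], "_", sub("-", "m", o[2]))
  fo <- c("mean", "median", "min", "max", "range", "variance", "sd",
          "skewness", "kurtosis", "p10", "p90", "iqr", "entropy",
          "uniformity")
  ha <- c("energy", "contrast", "correlation", "variance", "idm",
          "sum_average", "sum_variance", "sum_entropy", "entropy",
          "diff_variance", "diff_entropy", "imc1", "imc2")
  rl <- c("sre", "lre", "gln", "rln", "rp", "lglre", "hglre", "srlgle",
          "srhgle", "lrlgle", "lrhgle")
  rows <- list(data.frame(name = paste0("fo_", fo), family = "first_order",
                          offset_dr = NA_integer_, offset_dc = NA_integer_))
  for (o in offs) {
    rows <- c(rows, list(data.frame(
      name = paste0("glcm_", ha, "_", off_tag(o)), family = "glcm",
      offset_dr = o[1], offset_dc = o[2])))
  }
  for (o in offs) {
    rows <- c(rows, list(data.frame(
      name = paste0("glrlm_", rl, "_", off_tag(o)), family = "glrlm",
      offset_dr = o[1], offset_dc = o[2])))
  }
  out <- do.call(rbind, rows)
  out$n_levels <- as.integer(n_levels)
  stopifnot(!anyDuplicated(out$name))
  class(out) <- c("feature_catalog", "data.frame")
  out
}

#' Extract the texture feature vector of one lesion
#'
#' Quantizes the ROI and evaluates every feature in the catalog:
#' first-order statistics on raw in-mask intensities, Haralick features of
#' the symmetric distance-1 co-occurrence matrix at four offsets, and
#' run-length features along four directions. Deterministic given the
#' pixels; all values are finite even for degenerate ROIs (single pixel,
#' constant intensity).
#'
#' @param image A [roi_image].
#' @param catalog A [feature_catalog()]; its `n_levels` controls
#'   quantization.
#' @return Named numeric vector of `nrow(catalog)` features, with
#'   attribute `source_id` carrying the lesion id.
#' @examples
#' img <- roi_image(matrix(rnorm(256), 16, 16), matrix(TRUE, 16, 16))
#' length(extract_features(img))  # 110
#' @export
extract_features <- function(image, catalog = feature_catalog()) {
  stopifnot(inherits(image, "roi_image"), inherits(catalog, "feature_catalog"))
  q <- quantize_roi(image, catalog$n_levels[1])
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  off_tag <- function(o) paste0(o[1], "_", sub("-", "m", o[2]))
  vals <- first_order_features(image, q)
  for (o in offs) {
    f <- haralick_features(glcm(q, o))
    names(f) <- paste0(names(f), "_", off_tag(o))
    vals <- c(vals, f)
  }
  for (o in offs) {
    f <- glrlm_features(glrlm(q, o))
    names(f) <- paste0(names(f), "_", off_tag(o))
    vals <- c(vals, f)
  }
  stopifnot(identical(names(vals), catalog$name))
  attr(vals, "source_id") <- image$id
  vals
}

#' Extract features for a list of lesions into a table
#'
#' @param images List of [roi_image] objects.
#' @param catalog A [feature_catalog()].
#' @return Data frame with one row per lesion: `patient_id` followed by the
#'   110 feature columns.
#' @export
extract_feature_table <- function(images, catalog = feature_catalog()) {
  stopifnot(length(images) > 0)
  mat <- vapply(images, function(im) as.numeric(extract_features(im, catalog)),
                numeric(nrow(catalog)))
  out <- as.data.frame(t(mat))
  names(out) <- catalog$name
  ids <- vapply(images, function(im) im$id, character(1))
  cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE), out)
}

#' Write a feature table with its catalog sidecar
#'
#' Writes `<path>` as CSV and `<path>` with suffix `_catalog.csv` recording
#' family, offset and gray-level count per feature.
#'
#' @param features Data frame from [extract_feature_table()].
#' @param path Output CSV path.
#' @param catalog The catalog used for extraction.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, catalog = feature_catalog()) {
  utils::write.csv(features, path, row.names = FALSE)
  side <- sub("\\.csv$", "", path)
  utils::write.csv(as.data.frame(catalog), paste0(side, "_catalog.csv"),
                   row.names = FALSE)
  invisible(path)
}
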