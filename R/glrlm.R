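#' Gray-level run-length matrix
#'
#' Counts maximal runs of identical quantized gray levels along a lattice
#' direction, restricted to the mask: a run ends where the level changes,
#' the image ends, or the mask is left. `R[g, l]` is the number of runs of
#' level `g` with length `l`.
#'
#' @param quantized A [quantize_roi] result.
#' @param direction One of `c(0, 1)` (horizontal), `c(1, 0)` (vertical),
#'   `c(1, 1)` (down-right diagonal) or `c(1, -1)` (down-left diagonal).
#' @return An `Ng x Lmax` matrix of class `glrlm` with attributes
#'   `direction` and `n_pixels` (in-mask pixels traversed).
#' @examples
#' img <- roi_image(matrix(c(1, 1, 2), 1, 3), matrix(TRUE, 1, 3))
#' glrlm(quantize_roi(img, 2), c(0, 1))
#' @export
glrlm <- function(quantized, direction) {
  stopifnot(inherits(quantized, "quantized_roi"))
  direction <- as.integer(direction)
  dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  if (!any(vapply(dirs, identical, logical(1), y = direction))) {
    stop_input("'direction' must be one of (0,1), (1,0), (1,1), (1,-1)")
  }
  lv <- quantized$levels
  if (!any(lv > 0L)) stop_input("mask is empty")
  ng <- quantized$n_levels

  # Flatten all lines along the direction into one vector with a level-0
  # separator between lines: a single rle then yields every maximal run
  # (level 0 both breaks runs and is dropped, so mask gaps and line
  # boundaries are handled identically).
  key <- paste(direction, collapse = ",")
  vec <- if (key == "1,0") {
    as.vector(rbind(lv, 0L))
  } else if (key == "0,1") {
    as.vector(rbind(t(lv), 0L))
  } else {
    grp <- if (key == "1,1") col(lv) - row(lv) else col(lv) + row(lv)
    unlist(lapply(split(lv, grp), c, 0L), use.names = FALSE)
  }
  r <- rle(vec)
  keep <- r$values > 0L
  vals <- r$values[keep]
  lens <- r$lengths[keep]
  lmax <- if (length(lens)) max(lens) else 1L
  counts <- tabulate((vals - 1L) + (lens - 1L) * ng + 1L, ng * lmax)
  R <- matrix(counts, ng, lmax)
  structure(R, class = c("glrlm", "matrix"), direction = direction,
            n_pixels = sum(lv > 0L))
}

#' Run-length features of a GLRLM
#'
#' Eleven Galloway-style descriptors: short/long run emphasis, gray-level
#' and run-length nonuniformity, run percentage, low/high gray-level run
#' emphasis, and the four joint short/long by low/high emphases. All are
#' normalized by the total number of runs; run percentage divides runs by
#' the in-mask pixels traversed.
#'
#' @param R A run-length matrix from [glrlm()] (rows = gray levels,
#'   columns = run lengths).
#' @return Named numeric vector of 11 features (names prefixed `glrlm_`).
#' @export
glrlm_features <- function(R) {
  np <- attr(R, "n_pixels")
  R <- unclass(as.matrix(R))
  nr_runs <- sum(R)
  if (nr_runs == 0) stop_input("run-length matrix contains no runs")
  if (is.null(np)) np <- sum(R * col(R))   # pixels traversed, if not recorded
  g <- row(R)
  l <- col(R)
  sre <- sum(R / l^2) / nr_runs
  lre <- sum(R * l^2) / nr_runs
  gln <- sum(rowSums(R)^2) / nr_runs
  rln <- sum(colSums(R)^2) / nr_runs
  rp <- nr_runs / np
  lglre <- sum(R / g^2) / nr_runs
  hglre <- sum(R * g^2) / nr_runs
  srlgle <- sum(R / (g^2 * l^2)) / nr_runs
  srhgle <- sum(R * g^2 / l^2) / nr_runs
  lrlgle <- sum(R * l^2 / g^2) / nr_runs
  lrhgle <- sum(R * g^2 * l^2) / nr_runs
  c(glrlm_sre = sre, glrlm_lre = lre, glrlm_gln = gln, glrlm_rln = rln,
    glrlm_rp = rp, glrlm_lglre = lglre, glrlm_hglre = hglre,
    glrlm_srlgle = srlgle, glrlm_srhgle = srhgle, glrlm_lrlgle = lrlgle,
    glrlm_lrhgle = lrhgle)
}
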