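#' Region-of-interest image
#'
#' Bundle one grayscale slice with a binary tumor mask. This is the unit of
#' texture extraction: all features are computed from the pixels where
#' `mask` is `TRUE`. Intensities are in arbitrary (HU-like) units.
#'
#' @param pixels Numeric matrix of intensities.
#' @param mask Logical (or 0/1) matrix of the same dimensions marking the
#'   tumor region; must contain at least one `TRUE` pixel.
#' @param id Character identifier for the lesion.
#' @return An object of class `roi_image` with elements `pixels`, `mask`
#'   and `id`.
#' @examples
#' img <- roi_image(matrix(rnorm(64), 8, 8), matrix(TRUE, 8, 8), id = "toy")
#' @export
roi_image <- function(pixels, mask, id = "roi") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (is.numeric(mask)) mask <- mask != 0
  mask <- as.matrix(mask)
  if (!identical(dim(pixels), dim(mask))) {
    stop_input("'pixels' and 'mask' must have identical dimensions")
  }
  if (!any(mask)) stop_input("mask is empty: at least one in-mask pixel required")
  if (any(!is.finite(pixels[mask]))) {
    stop_input("non-finite intensities inside the mask")
  }
  structure(list(pixels = pixels, mask = mask, id = as.character(id)),
            class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image '%s'> %d x %d pixels, %d in mask (%.1f%%)\n",
              x$id, nrow(x$pixels), ncol(x$pixels), sum(x$mask),
              100 * mean(x$mask)))
  rng <- range(x$pixels[x$mask])
  cat(sprintf("  in-mask intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Read an image and mask pair from PNG files
#'
#' Grayscale PNGs are mapped back to their stored integer range (16-bit
#' images to 0..65535); masks are any nonzero pixel. Multichannel images are
#' averaged to one channel.
#'
#' @param image_path,mask_path Paths to PNG files of identical size.
#' @param id Lesion identifier; defaults to the image file name.
#' @return A [roi_image].
#' @export
read_roi_png <- function(image_path, mask_path, id = NULL) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_input("reading PNG images requires the 'png' package")
  }
  read1 <- function(path) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
    a
  }
  px <- read1(image_path) * 65535
  mk <- read1(mask_path) > 0
  roi_image(px, mk, id = id %||% sub("\\.png$", "", basename(image_path)))
}

#' Read an image and mask pair from NIfTI files
#'
#' Three-dimensional volumes are reduced to the single slice with the
#' largest mask area (the largest cross-sectional area of the tumor), which
#' is the slice the texture features are defined on.
#'
#' @param image_path,mask_path Paths to NIfTI files (`.nii` or `.nii.gz`).
#' @param id Lesion identifier; defaults to the image file name.
#' @return A [roi_image] for the mask-maximal slice.
#' @export
read_roi_nifti <- function(image_path, mask_path, id = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop_input("reading NIfTI images requires the 'RNifti' package")
  }
  px <- as.array(RNifti::readNifti(image_path))
  mk <- as.array(RNifti::readNifti(mask_path)) != 0
  if (length(dim(px)) == 3L) {
    areas <- apply(mk, 3, sum)
    k <- which.max(areas)
    px <- px[, , k]
    mk <- mk[, , k]
  }
  roi_image(px, mk, id = id %||% sub("\\.nii(\\.gz)?$", "", basename(image_path)))
}
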