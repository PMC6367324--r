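#' Region-of-interest image
#'
#' Container for a single-modality 2D tumour region of interest: an intensity
#' grid in scanner-arbitrary units together with a same-shape binary mask
#' marking the in-ROI pixels. All texture features are computed from the
#' in-mask pixels only.
#'
#' @param intensities Numeric matrix of finite, nonnegative intensities.
#' @param mask Logical (or 0/1) matrix of the same shape; `TRUE` marks in-ROI
#'   pixels. At least 16 pixels must be in-mask.
#'
#' @return An object of class `roi_image` with elements `intensities` and
#'   `mask`.
#' @examples
#' img <- roi_image(matrix(runif(64 * 64), 64), matrix(TRUE, 64, 64))
#' sum(img$mask)
#' @export
roi_image <- function(intensities, mask = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop_invalid("intensities must be a numeric matrix")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(intensities), ncol(intensities))
  if (!all(dim(mask) == dim(intensities))) {
    stop_invalid("mask and intensities must have identical dimensions")
  }
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (anyNA(mask)) stop_invalid("mask must be binary with no missing values")
  n_in <- sum(mask)
  if (n_in < 16L) stop_invalid("mask must contain at least 16 pixels, got ", n_in)
  vals <- intensities[mask]
  if (!all(is.finite(vals))) stop_invalid("in-mask intensities must be finite")
  if (any(vals < 0)) stop_invalid("in-mask intensities must be nonnegative")
  structure(list(intensities = intensities, mask = mask), class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  v <- x$intensities[x$mask]
  cat(sprintf(
    "<roi_image> %d x %d grid, %d in-mask pixels, intensity range [%.4g, %.4g]\n",
    nrow(x$intensities), ncol(x$intensities), sum(x$mask), min(v), max(v)
  ))
  invisible(x)
}

mask_values <- function(roi) roi$intensities[roi$mask]
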