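#' Quantize an ROI image to discrete gray levels
#'
#' Linear min-max binning of the in-mask intensities into `levels` equal-width
#' bins coded 0..levels-1. The in-mask maximum maps to `levels - 1`; a
#' constant image maps entirely to bin 0. Out-of-mask pixels are set to `NA`
#' so downstream pair counting can reject them.
#'
#' @param roi A [roi_image()].
#' @param levels Number of gray levels, at least 2.
#'
#' @return Integer matrix of codes in `0:(levels - 1)` with `NA` outside the
#'   mask; attribute `levels` records the bin count.
#' @examples
#' q <- quantize(roi_image(matrix(runif(400), 20), matrix(TRUE, 20, 20)), 8)
#' range(q, na.rm = TRUE)
#' @export
quantize <- function(roi, levels) {
  if (!inherits(roi, "roi_image")) stop_invalid("roi must be an roi_image")
  if (length(levels) != 1L || !is.finite(levels) || levels < 2) {
    stop_invalid("levels must be a single integer >= 2")
  }
  levels <- as.integer(levels)
  v <- roi$intensities
  inv <- v[roi$mask]
  lo <- min(inv)
  hi <- max(inv)
  q <- matrix(NA_integer_, nrow(v), ncol(v))
  if (hi > lo) {
    codes <- floor((v[roi$mask] - lo) / (hi - lo) * levels)
    codes[codes >= levels] <- levels - 1L
    q[roi$mask] <- as.integer(codes)
  } else {
    q[roi$mask] <- 0L
  }
  attr(q, "levels") <- levels
  q
}
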