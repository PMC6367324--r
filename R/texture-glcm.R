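# Gray-level co-occurrence and difference matrices.
#
# Coordinate convention: matrices are indexed (row, col) with the origin at
# the top-left; an offset (dy, dx) pairs pixel (r, c) with (r + dy, c + dx).
# A pair counts only when BOTH pixels are in-mask. The four unit-distance
# directions 0, 45, 90, 135 degrees are (0,1), (-1,1), (-1,0), (-1,-1).

unit_offsets <- function() list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

# Extract the two aligned code vectors for an offset, NA-pairs removed.
offset_pairs <- function(qimg, offset) {
  dy <- as.integer(offset[1]); dx <- as.integer(offset[2])
  if (dy == 0L && dx == 0L) stop_invalid("offset must be nonzero")
  nr <- nrow(qimg); nc <- ncol(qimg)
  r1 <- max(1L, 1L - dy):min(nr, nr - dy)
  c1 <- max(1L, 1L - dx):min(nc, nc - dx)
  if (!length(r1) || !length(c1)) return(cbind(integer(0), integer(0)))
  a <- qimg[r1, c1, drop = FALSE]
  b <- qimg[r1 + dy, c1 + dx, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  cbind(a[keep], b[keep])
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered in-mask pixel pairs at a spatial offset, symmetrizes by
#' adding the transpose, and normalizes to a joint probability matrix. Entries
#' are indexed by gray level 0..levels-1.
#'
#' @param qimg Quantized image from [quantize()] (integer codes, `NA` outside
#'   the mask).
#' @param offset Integer `(dy, dx)` pixel offset, not `(0, 0)`.
#' @param levels Gray-level count; defaults to the `levels` attribute of
#'   `qimg`.
#'
#' @return A `glcm` object: `levels` x `levels` probability matrix (sums to
#'   1, symmetric).
#' @examples
#' q <- quantize(roi_image(matrix(runif(400), 20)), 8)
#' g <- compute_glcm(q, c(0, 1))
#' sum(g$probabilities)
#' @export
compute_glcm <- function(qimg, offset, levels = attr(qimg, "levels")) {
  if (is.null(levels)) stop_invalid("levels missing and not an attribute of qimg")
  levels <- as.integer(levels)
  pr <- offset_pairs(qimg, offset)
  if (nrow(pr) == 0L) stop_invalid("no valid in-mask pixel pair at this offset")
  counts <- matrix(0, levels, levels)
  idx <- pr[, 1] * levels + pr[, 2] + 1L
  tab <- tabulate(idx, nbins = levels * levels)
  counts <- matrix(tab, levels, levels, byrow = TRUE)
  counts <- counts + t(counts)
  structure(
    list(levels = levels, probabilities = counts / sum(counts)),
    class = "glcm"
  )
}

#' Haralick-style GLCM features
#'
#' Computes 20 features of a symmetric, normalized gray-level co-occurrence
#' matrix: energy (angular second moment), entropy (base 2), correlation,
#' contrast (inertia), homogeneity (inverse difference moment), dissimilarity,
#' cluster shade, cluster prominence, maximum probability, sum
#' average/variance/entropy, difference average/variance/entropy,
#' autocorrelation, joint mean, joint variance, inverse difference and
#' normalized inverse difference. Correlation is defined as 0 when a marginal
#' variance is 0.
#'
#' @param glcm A `glcm` object from [compute_glcm()].
#' @return Named numeric vector of length 20.
#' @export
glcm_features <- function(glcm) {
  p <- glcm$probabilities
  L <- glcm$levels
  i <- matrix(0:(L - 1), L, L)            # row index = first gray level
  j <- t(i)
  px <- rowSums(p)
  mu_x <- sum((0:(L - 1)) * px)
  var_x <- sum(((0:(L - 1)) - mu_x)^2 * px)
  # symmetric matrix: both marginals identical
  d <- abs(i - j)
  s <- i + j
  p_pos <- p[p > 0]

  # sum distribution over k = i + j (0 .. 2L-2)
  ps <- vapply(0:(2 * L - 2), function(k) sum(p[s == k]), numeric(1))
  sum_avg <- sum((0:(2 * L - 2)) * ps)
  sum_var <- sum(((0:(2 * L - 2)) - sum_avg)^2 * ps)
  ps_pos <- ps[ps > 0]
  # difference distribution over k = |i - j| (0 .. L-1)
  pd <- vapply(0:(L - 1), function(k) sum(p[d == k]), numeric(1))
  diff_avg <- sum((0:(L - 1)) * pd)
  diff_var <- sum(((0:(L - 1)) - diff_avg)^2 * pd)
  pd_pos <- pd[pd > 0]

  corr <- if (var_x > 0) sum((i - mu_x) * (j - mu_x) * p) / var_x else 0

  out <- c(
    sum(p^2),
    -sum(p_pos * log2(p_pos)),
    corr,
    sum(d^2 * p),
    sum(p / (1 + d^2)),
    sum(d * p),
    sum((s - 2 * mu_x)^3 * p),
    sum((s - 2 * mu_x)^4 * p),
    max(p),
    sum_avg,
    sum_var,
    -sum(ps_pos * log2(ps_pos)),
    diff_avg,
    diff_var,
    -sum(pd_pos * log2(pd_pos)),
    sum(i * j * p),
    mu_x,
    var_x,
    sum(p / (1 + d)),
    sum(p / (1 + d / L))
  )
  names(out) <- glcm_feature_names()
  out
}

#' Gray-level difference vector
#'
#' Distribution of absolute gray-level differences `|g(p) - g(p + disp)|`
#' over all in-mask pixel pairs at a displacement, normalized to sum 1.
#'
#' @param qimg Quantized image from [quantize()].
#' @param displacement Integer `(dy, dx)`, not `(0, 0)`.
#' @param levels Gray-level count; defaults to the attribute of `qimg`.
#'
#' @return A `gldm` object with `levels` and `probabilities` (length
#'   `levels`, over differences 0..levels-1).
#' @export
compute_gldm <- function(qimg, displacement, levels = attr(qimg, "levels")) {
  if (is.null(levels)) stop_invalid("levels missing and not an attribute of qimg")
  levels <- as.integer(levels)
  pr <- offset_pairs(qimg, displacement)
  if (nrow(pr) == 0L) stop_invalid("no valid in-mask pixel pair at this displacement")
  dd <- abs(pr[, 1] - pr[, 2])
  counts <- tabulate(dd + 1L, nbins = levels)
  structure(
    list(levels = levels, probabilities = counts / sum(counts)),
    class = "gldm"
  )
}

#' Gray-level difference features
#'
#' Computes 8 features of a gray-level difference distribution: difference
#' mean, variance, entropy (base 2), energy, contrast (second raw moment),
#' inverse difference moment, maximum probability and the zero-difference
#' fraction.
#'
#' @param gldm A `gldm` object from [compute_gldm()].
#' @return Named numeric vector of length 8.
#' @export
gldm_features <- function(gldm) {
  p <- gldm$probabilities
  dvals <- 0:(gldm$levels - 1)
  m <- sum(dvals * p)
  contrast <- sum(dvals^2 * p)
  p_pos <- p[p > 0]
  out <- c(
    m,
    contrast - m^2,
    -sum(p_pos * log2(p_pos)),
    sum(p^2),
    contrast,
    sum(p / (1 + dvals^2)),
    max(p),
    p[1]
  )
  names(out) <- gldm_feature_names()
  out
}
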