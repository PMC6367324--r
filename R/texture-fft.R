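# Fourier power-spectrum features.

fft_freqs <- function(n) {
  # DFT frequencies in cycles/pixel, standard (unshifted) order
  k <- c(0:floor((n - 1) / 2), -(floor(n / 2):1))
  k / n
}

#' Fourier power-spectrum features
#'
#' Computes 12 spectral features of an ROI. The mask bounding box is taken,
#' out-of-mask pixels are replaced by the in-mask mean (mean-fill avoids the
#' mask edge dominating the spectrum), the mean is subtracted, and the 2D DFT
#' power spectrum is formed. With the non-DC power normalized to a
#' distribution, the features are: total non-DC power (per pixel, i.e. the
#' variance of the filled box), spectral entropy (base 2), the energy
#' fractions of 4 equal-width radial annuli, the dominant radial frequency
#' (centre of the highest-energy annulus), the power-weighted mean and sd of
#' radial frequency, spectral flatness (geometric / arithmetic mean power),
#' anisotropy (dominant 45-degree sector power over mean sector power), and
#' the low-frequency power fraction at the half-Nyquist split
#' (`low / (low + high)`, radius 0.25 cycles/pixel).
#'
#' For a spectrally empty image (constant intensities) all 12 features are 0
#' by convention.
#'
#' @param roi A [roi_image()].
#' @return Named numeric vector of length 12.
#' @export
fft_features <- function(roi) {
  if (!inherits(roi, "roi_image")) stop_invalid("roi must be an roi_image")
  rr <- range(which(rowSums(roi$mask) > 0))
  cc <- range(which(colSums(roi$mask) > 0))
  box <- roi$intensities[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  mbox <- roi$mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  m <- mean(box[mbox])
  box[!mbox] <- m
  x <- box - mean(box)

  nr <- nrow(x); nc <- ncol(x)
  pw <- Mod(stats::fft(x))^2 / (nr * nc)^2
  fy <- matrix(fft_freqs(nr), nr, nc)
  fx <- matrix(fft_freqs(nc), nr, nc, byrow = TRUE)
  r <- sqrt(fy^2 + fx^2)
  nondc <- r > 0
  total <- sum(pw[nondc])

  out <- stats::setNames(numeric(12), fft_feature_names())
  if (total <= (1e-12 * (abs(m) + 1))^2) {
    return(out)
  }

  p <- pw[nondc] / total
  rv <- r[nondc]
  rmax <- max(rv)
  band_id <- pmin(4L, floor(rv / rmax * 4) + 1L)
  bands <- vapply(1:4, function(b) sum(p[band_id == b]), numeric(1))
  centers <- rmax * (2 * (1:4) - 1) / 8
  mean_f <- sum(p * rv)
  sd_f <- sqrt(max(0, sum(p * rv^2) - mean_f^2))
  p_pos <- p[p > 0]
  # sectors of 45 degrees on orientation modulo 180
  th <- atan2(fy[nondc], fx[nondc]) %% pi
  sec_id <- pmin(4L, floor(th / pi * 4) + 1L)
  sec <- vapply(1:4, function(s2) sum(p[sec_id == s2]), numeric(1))
  low <- sum(p[rv < 0.25])

  out["fft_total_power"] <- total
  out["fft_spectral_entropy"] <- -sum(p_pos * log2(p_pos))
  out[c("fft_band1", "fft_band2", "fft_band3", "fft_band4")] <- bands
  out["fft_dominant_freq"] <- centers[which.max(bands)]
  out["fft_mean_freq"] <- mean_f
  out["fft_sd_freq"] <- sd_f
  out["fft_spectral_flatness"] <- exp(mean(log(pmax(p, 1e-300)))) / mean(p)
  out["fft_anisotropy"] <- max(sec) / mean(sec)
  out["fft_low_high_ratio"] <- low
  out
}
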