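# The frozen radiomic feature manifest.
#
# 55 features per modality: 15 first-order histogram features, 20 gray-level
# co-occurrence matrix (GLCM) features averaged over the four unit-distance
# directions, 8 gray-level difference matrix (GLDM) features averaged the same
# way, and 12 Fourier power-spectrum features. Per patient the T2W-like block
# precedes the ADC-like block, giving 110 names. Extraction output is tested
# against the golden copy in inst/extdata/feature_manifest.txt; changing a
# name or the order is a breaking change.

hist_feature_names <- function() {
  c(
    "hist_mean", "hist_sd", "hist_variance", "hist_skewness", "hist_kurtosis",
    "hist_min", "hist_max", "hist_range", "hist_median",
    "hist_p10", "hist_p25", "hist_p75", "hist_p90",
    "hist_entropy", "hist_uniformity"
  )
}

glcm_feature_names <- function() {
  c(
    "glcm_energy", "glcm_entropy", "glcm_correlation", "glcm_contrast",
    "glcm_homogeneity", "glcm_dissimilarity", "glcm_cluster_shade",
    "glcm_cluster_prominence", "glcm_max_probability", "glcm_sum_average",
    "glcm_sum_variance", "glcm_sum_entropy", "glcm_difference_average",
    "glcm_difference_variance", "glcm_difference_entropy",
    "glcm_autocorrelation", "glcm_joint_mean", "glcm_joint_variance",
    "glcm_inverse_difference", "glcm_inverse_difference_norm"
  )
}

gldm_feature_names <- function() {
  c(
    "gldm_mean", "gldm_variance", "gldm_entropy", "gldm_energy",
    "gldm_contrast", "gldm_idm", "gldm_max_probability", "gldm_zero_fraction"
  )
}

fft_feature_names <- function() {
  c(
    "fft_total_power", "fft_spectral_entropy",
    "fft_band1", "fft_band2", "fft_band3", "fft_band4",
    "fft_dominant_freq", "fft_mean_freq", "fft_sd_freq",
    "fft_spectral_flatness", "fft_anisotropy", "fft_low_high_ratio"
  )
}

#' Canonical radiomic feature manifest
#'
#' Returns the frozen, ordered feature names produced by the extraction
#' pipeline: 15 histogram + 20 GLCM + 8 GLDM + 12 FFT features per modality
#' (55), optionally prefixed and concatenated for the two modalities (110 per
#' patient, T2W block first).
#'
#' @param per_patient If `TRUE` (default) return the 110 modality-prefixed
#'   per-patient names (`t2w_*` then `adc_*`); otherwise the 55 unprefixed
#'   per-modality names.
#'
#' @return Character vector of length 110 or 55.
#' @examples
#' length(feature_manifest())            # 110
#' length(feature_manifest(FALSE))       # 55
#' @export
feature_manifest <- function(per_patient = TRUE) {
  base <- c(
    hist_feature_names(), glcm_feature_names(),
    gldm_feature_names(), fft_feature_names()
  )
  stopifnot(length(base) == 55L)
  if (!per_patient) return(base)
  c(paste0("t2w_", base), paste0("adc_", base))
}
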