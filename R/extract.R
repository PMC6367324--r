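#' Extract the 55-feature texture vector of one modality
#'
#' Runs the four feature families on a masked ROI and concatenates them in
#' manifest order: 15 histogram features, 20 GLCM features and 8 GLDM
#' features averaged over the four unit-distance directions (0, 45, 90 and
#' 135 degrees), and 12 Fourier spectrum features.
#'
#' @param roi A [roi_image()].
#' @param levels_glcm Gray-level count for GLCM/GLDM quantization (default
#'   32).
#' @param levels_hist Bin count for the histogram entropy/uniformity features
#'   (default 64).
#'
#' @return Named numeric vector of length 55 in [feature_manifest()] order
#'   (unprefixed).
#' @export
extract_modality <- function(roi, levels_glcm = 32L, levels_hist = 64L) {
  q <- quantize(roi, levels_glcm)
  offs <- unit_offsets()
  glcm_mat <- vapply(offs, function(o) glcm_features(compute_glcm(q, o)),
                     numeric(20))
  gldm_mat <- vapply(offs, function(o) gldm_features(compute_gldm(q, o)),
                     numeric(8))
  out <- c(
    histogram_features(roi, levels = levels_hist),
    rowMeans(glcm_mat),
    rowMeans(gldm_mat),
    fft_features(roi)
  )
  stopifnot(identical(names(out), feature_manifest(per_patient = FALSE)))
  out
}

#' Extract the 110-feature vector of one patient
#'
#' Concatenates the 55 T2W-like features followed by the 55 ADC-like
#' features, with modality-prefixed names.
#'
#' @param t2w,adc [roi_image()] objects for the two modalities.
#' @inheritParams extract_modality
#' @return Named numeric vector of length 110 in [feature_manifest()] order.
#' @export
extract_patient <- function(t2w, adc, levels_glcm = 32L, levels_hist = 64L) {
  v <- c(
    extract_modality(t2w, levels_glcm, levels_hist),
    extract_modality(adc, levels_glcm, levels_hist)
  )
  names(v) <- feature_manifest()
  v
}

#' Extract a feature table for a whole cohort
#'
#' Applies [extract_patient()] to every patient and assembles a feature
#' table: one row per patient with the 110 manifest columns, the risk
#' `label`, and the ordinal `pirads` score when present.
#'
#' @param patients List of patients as produced by [generate_cohort()] or
#'   [read_cohort()]: each element has `patient_id`, `t2w`, `adc`, `label`
#'   and optionally `pirads`.
#' @inheritParams extract_modality
#' @return A `data.frame` with `patient_id`, 110 feature columns, `label`
#'   (factor with levels `lower`, `high`) and optionally `pirads`.
#' @export
extract_cohort <- function(patients, levels_glcm = 32L, levels_hist = 64L) {
  feats <- t(vapply(
    patients,
    function(p) extract_patient(p$t2w, p$adc, levels_glcm, levels_hist),
    numeric(110)
  ))
  tab <- data.frame(
    patient_id = vapply(patients, function(p) p$patient_id, character(1)),
    feats,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  tab$label <- as_risk_factor(vapply(patients, function(p) as.character(p$label),
                                     character(1)))
  if (!is.null(patients[[1]]$pirads)) {
    tab$pirads <- vapply(patients, function(p) as.integer(p$pirads), integer(1))
  }
  tab
}

# Internal: split a feature table into the X matrix (manifest order enforced)
# and the label factor.
table_xy <- function(table) {
  manifest <- intersect(feature_manifest(), names(table))
  if (length(manifest) == 0L) {
    # feature-shortcut tables may carry arbitrary feature names: everything
    # except bookkeeping columns
    manifest <- setdiff(names(table), c("patient_id", "label", "pirads"))
  }
  x <- as.matrix(table[, manifest, drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x)) stop_invalid("feature table contains missing values")
  list(x = x, y = as_risk_factor(table$label), feature_names = manifest)
}
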