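#' Write a cohort to disk
#'
#' Writes one 16-bit single-channel TIFF per modality per patient, one 8-bit
#' PNG mask (values 0/255) per patient, and a CSV manifest with columns
#' `patient_id,t2w_path,adc_path,mask_path,label,pirads`. Intensities are
#' integers in 0..65535, so the round trip through [read_cohort()] is
#' lossless.
#'
#' @param patients Cohort list as from [generate_cohort()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(patients, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop_invalid("cannot create directory ", directory)
  rows <- lapply(patients, function(p) {
    t2w_path <- file.path(directory, paste0(p$patient_id, "_t2w.tiff"))
    adc_path <- file.path(directory, paste0(p$patient_id, "_adc.tiff"))
    mask_path <- file.path(directory, paste0(p$patient_id, "_mask.png"))
    if (!identical(dim(p$t2w$mask), dim(p$adc$mask)) ||
        !identical(p$t2w$mask, p$adc$mask)) {
      # masks may legitimately differ per modality; store the t2w mask and
      # require equality for the single-mask manifest layout
      stop_invalid("write_cohort expects identical masks across modalities")
    }
    tiff::writeTIFF(p$t2w$intensities / 65535, t2w_path, bits.per.sample = 16L)
    tiff::writeTIFF(p$adc$intensities / 65535, adc_path, bits.per.sample = 16L)
    png::writePNG(p$t2w$mask * 1.0, mask_path)
    data.frame(
      patient_id = p$patient_id,
      t2w_path = basename(t2w_path), adc_path = basename(adc_path),
      mask_path = basename(mask_path),
      label = as.character(p$label), pirads = as.integer(p$pirads),
      stringsAsFactors = FALSE
    )
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}

read_gray <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Read a cohort manifest back into memory
#'
#' @param manifest_path Path to a `manifest.csv` written by [write_cohort()].
#' @return List of patients in the same shape as [generate_cohort()] output.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    mask <- read_gray(file.path(base, row$mask_path)) > 0.5
    list(
      patient_id = row$patient_id,
      t2w = roi_image(round(read_gray(file.path(base, row$t2w_path)) * 65535), mask),
      adc = roi_image(round(read_gray(file.path(base, row$adc_path)) * 65535), mask),
      label = row$label,
      pirads = as.integer(row$pirads)
    )
  })
}

#' Write / read a feature table as CSV
#'
#' @param table Feature table (`data.frame` with manifest columns + `label`).
#' @param path CSV path.
#' @return `write_feature_table` returns the path invisibly;
#'   `read_feature_table` the table with `label` as a risk factor.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  tab$label <- as_risk_factor(tab$label)
  tab
}
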