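#' Train the final threshold-calibrated classifier
#'
#' Fits the chosen learner on the (by default oversampled) full development
#' set and sets the decision threshold to the arithmetic mean of the per-run
#' thresholds that maximized the high-risk F-measure for that algorithm in
#' cross-validation.
#'
#' @param spec A [learner_spec()] for the selected algorithm.
#' @param table Development feature table.
#' @param results `run_results` from [run_cv()] containing the algorithm.
#' @param oversample Fit on the oversampled development set (default `TRUE`,
#'   consistent with CV training).
#' @return A `final_classifier`: `model`, `threshold`, and
#'   `threshold_provenance` (the per-run thresholds averaged).
#' @export
train_final <- function(spec, table, results, oversample = TRUE) {
  m <- results$metrics[results$metrics$algorithm == spec$algorithm, ]
  if (nrow(m) == 0L) {
    stop_invalid("results contain no runs for algorithm ", spec$algorithm)
  }
  thresholds <- m$threshold_star[order(m$run)]
  train <- if (oversample) {
    random_oversample(table, derive_seed(results$base_seed, 991L))
  } else table
  structure(
    list(
      model = fit_learner(spec, train),
      threshold = mean(thresholds),
      threshold_provenance = thresholds
    ),
    class = "final_classifier"
  )
}

#' Apply the final classifier to a cohort
#'
#' Scores every row and binarizes at the calibrated threshold: predicted
#' high-risk iff `score >= threshold`.
#'
#' @param final A `final_classifier` from [train_final()].
#' @param table Feature table with matching manifest.
#' @return List with `predictions` (a [prediction_set()] against the table's
#'   labels) and `predicted_labels` (risk factor).
#' @export
apply_classifier <- function(final, table) {
  s <- score(final$model, table)
  ids <- if (!is.null(table$patient_id)) table$patient_id else
    as.character(seq_len(nrow(table)))
  list(
    predictions = prediction_set(s, table$label, ids),
    predicted_labels = factor(ifelse(s >= final$threshold, "high", "lower"),
                              levels = risk_levels()),
    threshold = final$threshold
  )
}
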