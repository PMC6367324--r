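#' Binarize an ordinal reader score
#'
#' Scores above 3 map to high risk; 3 and below to lower risk. (The 4-5 =
#' high convention is the one consistent with typical class-mean spacing of
#' the two risk groups on the 1-5 scale; see the methods vignette.)
#'
#' @param score Integer score(s) in 1..5.
#' @return Risk factor of the same length.
#' @export
pirads_binarize <- function(score) {
  score <- as.integer(score)
  if (any(!score %in% 1:5)) stop_invalid("scores must be integers in 1..5")
  factor(ifelse(score > 3L, "high", "lower"), levels = risk_levels())
}

#' Evaluate the ordinal-score comparator
#'
#' AUC treats the raw ordinal score as the ranking score (ties credited
#' 0.5); the per-class precision/recall/F come from the binarized (>3)
#' labels.
#'
#' @param scores Ordinal scores 1..5.
#' @param labels True risk classes.
#' @return Named vector of the seven measures.
#' @export
pirads_evaluate <- function(scores, labels) {
  labels <- as_risk_factor(labels)
  auc <- roc_auc(prediction_set((as.integer(scores) - 1) / 4, labels))
  c(auc = auc, binary_prf(pirads_binarize(scores), labels))
}

# The seven measures of a fixed classifier on one labelled cohort: ranking
# AUC plus per-class P/R/F at the calibrated threshold.
thresholded_measures <- function(scores, labels, threshold) {
  labels <- as_risk_factor(labels)
  pred <- factor(ifelse(scores >= threshold, "high", "lower"),
                 levels = risk_levels())
  c(auc = roc_auc(prediction_set(scores, labels)), binary_prf(pred, labels))
}

#' Label-permutation null benchmark
#'
#' Evaluates the fixed final classifier on `replicates` copies of the
#' validation cohort whose labels have been randomly permuted (class counts
#' preserved), breaking any feature-label relationship. Returns per-measure
#' mean, sd and standard error `sd / sqrt(replicates)`.
#'
#' @param final A `final_classifier`.
#' @param table Validation feature table.
#' @param replicates Number of permuted copies (default 100).
#' @param seed Integer seed.
#' @return List with `summary` (data.frame: measure, mean, sd, se) and the
#'   `replicates` x 7 matrix `values`.
#' @export
permutation_benchmark <- function(final, table, replicates = 100L, seed = 1L) {
  scores <- score(final$model, table)
  labels <- as_risk_factor(table$label)
  vals <- with_seed(derive_seed(seed, 71L), {
    t(vapply(seq_len(replicates), function(i) {
      thresholded_measures(scores, sample(labels), final$threshold)
    }, numeric(7)))
  })
  list(
    summary = data.frame(
      measure = colnames(vals),
      mean = colMeans(vals),
      sd = apply(vals, 2, stats::sd),
      se = apply(vals, 2, stats::sd) / sqrt(replicates),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    values = vals,
    replicates = as.integer(replicates)
  )
}

#' Paired bootstrap comparison of classifier and comparator
#'
#' Resamples the validation cohort with replacement `replicates` times (a
#' draw that loses a class is redrawn, since AUC would be undefined),
#' computes all seven measures for both methods on each resample, and tests
#' each measure's paired difference across the bootstrap blocks with the
#' k = 2 Friedman test.
#'
#' @param classifier_scores Numeric high-risk scores of the classifier.
#' @param classifier_threshold Binarization threshold for the classifier.
#' @param comparator_scores Ordinal 1..5 comparator scores.
#' @param labels True risk classes (shared sample order for both methods).
#' @param replicates Bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return List with `p_values` (named per measure), and per-measure
#'   bootstrap matrices `classifier` and `comparator`.
#' @export
bootstrap_compare <- function(classifier_scores, classifier_threshold,
                              comparator_scores, labels,
                              replicates = 100L, seed = 1L) {
  labels <- as_risk_factor(labels)
  n <- length(labels)
  stopifnot(length(classifier_scores) == n, length(comparator_scores) == n)
  cls_vals <- matrix(NA_real_, replicates, 7)
  cmp_vals <- matrix(NA_real_, replicates, 7)
  with_seed(derive_seed(seed, 137L), {
    for (i in seq_len(replicates)) {
      repeat {
        idx <- sample(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
      }
      cls_vals[i, ] <- thresholded_measures(classifier_scores[idx],
                                            labels[idx], classifier_threshold)
      cmp_vals[i, ] <- pirads_evaluate(comparator_scores[idx], labels[idx])
    }
  })
  colnames(cls_vals) <- colnames(cmp_vals) <- measure_names()
  p <- vapply(measure_names(), function(msr) {
    rk <- t(apply(cbind(cls_vals[, msr], cmp_vals[, msr]), 1, function(x) rank(-x)))
    friedman_test(rk)$p_value
  }, numeric(1))
  list(p_values = p, classifier = cls_vals, comparator = cmp_vals,
       replicates = replicates)
}

#' Assemble the benchmark report
#'
#' Builds the three-row comparison table: the final classifier (with the
#' paired-bootstrap p-values in parentheses), the ordinal-score comparator,
#' and the permutation-null row (with standard errors in parentheses), over
#' AUC and the per-class F/P/R measures.
#'
#' @param classifier_measures Named 7-vector from `thresholded_measures()`.
#' @param comparator_measures Named 7-vector from [pirads_evaluate()].
#' @param permutation Result of [permutation_benchmark()].
#' @param comparison Result of [bootstrap_compare()].
#' @return A `benchmark_report` with `table` (data.frame), `markdown`
#'   (character), and the raw components; `as_json()`-able via
#'   [report_json()].
#' @export
build_report <- function(classifier_measures, comparator_measures,
                         permutation, comparison) {
  msr <- measure_names()
  perm_mean <- stats::setNames(permutation$summary$mean, permutation$summary$measure)
  perm_se <- stats::setNames(permutation$summary$se, permutation$summary$measure)
  fmt <- function(v, extra) sprintf("%.3f (%.3g)", v, extra)
  tab <- data.frame(
    method = c("classifier", "comparator", "permutation_null"),
    rbind(classifier_measures[msr], comparator_measures[msr], perm_mean[msr]),
    stringsAsFactors = FALSE
  )
  disp <- rbind(
    fmt(classifier_measures[msr], comparison$p_values[msr]),
    sprintf("%.3f", comparator_measures[msr]),
    fmt(perm_mean[msr], perm_se[msr])
  )
  md <- c(
    paste0("| method | ", paste(msr, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(msr) + 1), collapse = "|"), "|"),
    paste0("| ", c("classifier", "comparator", "permutation null"), " | ",
           apply(disp, 1, paste, collapse = " | "), " |")
  )
  structure(
    list(table = tab, markdown = paste(md, collapse = "\n"),
         classifier = classifier_measures, comparator = comparator_measures,
         permutation = permutation, comparison = comparison),
    class = "benchmark_report"
  )
}

#' Serialize a benchmark report to JSON
#'
#' @param report A `benchmark_report`.
#' @param path Optional file path; when given, writes and returns the path.
#' @return JSON string, or `path` invisibly.
#' @export
report_json <- function(report, path = NULL) {
  obj <- list(
    classifier = as.list(report$classifier),
    comparator = as.list(report$comparator),
    permutation_null = report$permutation$summary,
    comparison_p = as.list(report$comparison$p_values)
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(x$markdown, "\n")
  invisible(x)
}
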