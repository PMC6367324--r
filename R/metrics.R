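#' Bundle scores and true labels into a prediction set
#'
#' @param scores Numeric high-risk scores in `[0, 1]` (finite).
#' @param labels True classes, `"high"` / `"lower"`.
#' @param sample_ids Optional identifiers (defaults to the row index).
#' @return A `prediction_set` object.
#' @export
prediction_set <- function(scores, labels, sample_ids = NULL) {
  labels <- as_risk_factor(labels)
  if (length(scores) != length(labels)) {
    stop_invalid("scores and labels must have equal length")
  }
  if (!all(is.finite(scores))) stop_invalid("scores must be finite")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(scores))
  structure(
    list(scores = as.numeric(scores), labels = labels,
         sample_ids = as.character(sample_ids)),
    class = "prediction_set"
  )
}

check_both_classes <- function(preds) {
  if (length(unique(preds$labels)) < 2L) {
    stop_invalid("both classes must be present")
  }
}

#' Area under the ROC curve
#'
#' Rank-statistic AUC: the probability that a randomly chosen high-risk
#' sample scores above a randomly chosen lower-risk one, with ties credited
#' 0.5 (equivalent to the normalized Wilcoxon-Mann-Whitney statistic).
#'
#' @param preds A [prediction_set()] containing both classes.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(prediction_set(c(.9, .8, .3, .2), c("high", "high", "lower", "lower")))
#' @export
roc_auc <- function(preds) {
  check_both_classes(preds)
  r <- rank(preds$scores)
  hi <- preds$labels == "high"
  n1 <- sum(hi); n0 <- sum(!hi)
  (sum(r[hi]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision, recall and F-measure at a fixed threshold
#'
#' Both class-specific metric sets derive from a single binarization of the
#' high-risk score: a sample is predicted high-risk iff `score >= threshold`,
#' and predicted lower-risk otherwise. Zero-denominator conventions:
#' precision is 0 with no predicted positives, and F is 0 when precision and
#' recall are both 0.
#'
#' @param preds A [prediction_set()].
#' @param threshold Score threshold in `[0, 1]`.
#' @param target_class Class treated as positive (`"high"` or `"lower"`).
#' @return Named vector `c(precision, recall, f)`.
#' @export
prf_at <- function(preds, threshold, target_class = "high") {
  if (threshold < 0 || threshold > 1) stop_invalid("threshold must be in [0, 1]")
  target_class <- match.arg(target_class, risk_levels())
  pred_pos <- if (target_class == "high") {
    preds$scores >= threshold
  } else {
    preds$scores < threshold
  }
  true_pos <- preds$labels == target_class
  tp <- sum(pred_pos & true_pos)
  fp <- sum(pred_pos & !true_pos)
  fn <- sum(!pred_pos & true_pos)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f = f)
}

#' Maximum F-measure over all thresholds
#'
#' Sweeps the binarization threshold over every distinct score value (plus
#' the 0 and 1 endpoints) and returns the maximum F-measure for the target
#' class together with the precision, recall and threshold attaining it.
#' Ties are broken toward the lowest threshold.
#'
#' @inheritParams prf_at
#' @return List with `f_max`, `p_max`, `r_max`, `threshold_star`,
#'   `target_class`.
#' @export
fmax_sweep <- function(preds, target_class = "high") {
  check_both_classes(preds)
  target_class <- match.arg(target_class, risk_levels())
  cand <- sort(unique(c(0, preds$scores, 1)))
  prf <- vapply(cand, function(t) prf_at(preds, t, target_class), numeric(3))
  best <- which.max(prf["f", ])          # which.max takes the first maximum
  list(
    f_max = unname(prf["f", best]), p_max = unname(prf["precision", best]),
    r_max = unname(prf["recall", best]), threshold_star = unname(cand[best]),
    target_class = target_class
  )
}

#' Full seven-measure evaluation of a prediction set
#'
#' AUC plus the maximum-F metrics (F_max, P_max, R_max) for each class as
#' the positive target.
#'
#' @param preds A [prediction_set()] with both classes present.
#' @return List with `auc`, `high_class` and `lower_class` (each a
#'   [fmax_sweep()] result).
#' @export
evaluate <- function(preds) {
  list(
    auc = roc_auc(preds),
    high_class = fmax_sweep(preds, "high"),
    lower_class = fmax_sweep(preds, "lower")
  )
}

# Flatten an evaluate() result to the 7 named measures used for ranking.
measure_names <- function() {
  c("auc", "fmax_high", "pmax_high", "rmax_high",
    "fmax_lower", "pmax_lower", "rmax_lower")
}

flatten_eval <- function(ev) {
  c(
    auc = ev$auc,
    fmax_high = ev$high_class$f_max, pmax_high = ev$high_class$p_max,
    rmax_high = ev$high_class$r_max,
    fmax_lower = ev$lower_class$f_max, pmax_lower = ev$lower_class$p_max,
    rmax_lower = ev$lower_class$r_max
  )
}

#' Evaluate fixed binary predictions
#'
#' Per-class precision/recall/F for already-binarized predictions (used for
#' the final thresholded classifier and the ordinal-score comparator).
#'
#' @param pred_labels Predicted classes (`"high"`/`"lower"`).
#' @param true_labels True classes.
#' @return Named vector with the six per-class P/R/F measures.
#' @export
binary_prf <- function(pred_labels, true_labels) {
  pred <- as_risk_factor(pred_labels)
  truth <- as_risk_factor(true_labels)
  one <- function(cls) {
    tp <- sum(pred == cls & truth == cls)
    fp <- sum(pred == cls & truth != cls)
    fn <- sum(pred != cls & truth == cls)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(f = f, precision = p, recall = r)
  }
  hi <- one("high"); lo <- one("lower")
  c(
    fmax_high = hi[["f"]], pmax_high = hi[["precision"]],
    rmax_high = hi[["recall"]],
    fmax_lower = lo[["f"]], pmax_lower = lo[["precision"]],
    rmax_lower = lo[["recall"]]
  )
}
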