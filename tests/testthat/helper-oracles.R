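# Independent brute-force oracles used across test files. These deliberately
# avoid the package's vectorized implementations.

# ROI with uniform random intensities and a random (but >= 16 px) mask.
random_roi <- function(n = 12, seed = 1) {
  set.seed(seed)
  repeat {
    mask <- matrix(runif(n * n) < 0.7, n, n)
    if (sum(mask) >= 16) break
  }
  roi_image(matrix(round(runif(n * n, 0, 100)), n, n), mask)
}

# Naive double-loop GLCM: count ordered pairs, symmetrize, normalize.
naive_glcm <- function(qimg, offset, levels) {
  counts <- matrix(0, levels, levels)
  dy <- offset[1]; dx <- offset[2]
  for (r in seq_len(nrow(qimg))) {
    for (c in seq_len(ncol(qimg))) {
      r2 <- r + dy; c2 <- c + dx
      if (r2 < 1 || r2 > nrow(qimg) || c2 < 1 || c2 > ncol(qimg)) next
      a <- qimg[r, c]; b <- qimg[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
    }
  }
  counts <- counts + t(counts)
  counts / sum(counts)
}

# Naive GLDM distribution over absolute differences.
naive_gldm <- function(qimg, disp, levels) {
  counts <- numeric(levels)
  dy <- disp[1]; dx <- disp[2]
  for (r in seq_len(nrow(qimg))) {
    for (c in seq_len(ncol(qimg))) {
      r2 <- r + dy; c2 <- c + dx
      if (r2 < 1 || r2 > nrow(qimg) || c2 < 1 || c2 > ncol(qimg)) next
      a <- qimg[r, c]; b <- qimg[r2, c2]
      if (is.na(a) || is.na(b)) next
      d <- abs(a - b)
      counts[d + 1] <- counts[d + 1] + 1
    }
  }
  counts / sum(counts)
}

# All-pairs AUC oracle with 0.5 tie credit.
pairs_auc <- function(scores, labels) {
  hi <- which(labels == "high"); lo <- which(labels == "lower")
  tot <- 0
  for (i in hi) for (j in lo) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(hi) * length(lo))
}

# Trapezoidal integration of the empirical ROC curve.
trapezoid_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(c(Inf, thr, -Inf), function(t) {
    pos <- scores >= t
    c(
      fpr = sum(pos & labels == "lower") / sum(labels == "lower"),
      tpr = sum(pos & labels == "high") / sum(labels == "high")
    )
  }, numeric(2)))
  sum(diff(pts[, "fpr"]) * (utils::head(pts[, "tpr"], -1) + utils::tail(pts[, "tpr"], -1)) / 2)
}

# Dense-grid maximum F oracle.
grid_fmax <- function(preds, target_class, grid = seq(0, 1, length.out = 1001)) {
  max(vapply(grid, function(t) prf_at(preds, t, target_class)[["f"]], numeric(1)))
}

random_prediction_set <- function(n = 40, seed = 1) {
  set.seed(seed)
  labels <- character(0)
  while (length(unique(labels)) < 2) {
    labels <- sample(c("high", "lower"), n, replace = TRUE, prob = c(0.3, 0.7))
  }
  # scores on a coarse decimal lattice: ties occur, and every achievable
  # thresholding is representable on the 1001-point oracle grid
  s <- round(runif(n), sample(c(1, 2), 1))
  prediction_set(s, labels)
}

small_shift_table <- function(n_high = 8, n_lower = 16, effect = 2, seed = 1) {
  generate_feature_table(
    cohort_spec(n_high, n_lower, effect_size = effect, seed = seed),
    n_informative = 20
  )
}
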