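#' Friedman test from a rank matrix
#'
#' Tie-corrected Friedman chi-square over a blocks-by-treatments rank matrix
#' (rows = CV runs, columns = algorithms; within-row average ranks for ties).
#' The p-value comes from the chi-square distribution with `k - 1` degrees of
#' freedom. When every row ties all treatments (tie correction degenerates to
#' 0/0) the statistic is defined as 0 and p as 1.
#'
#' @param rank_matrix Numeric matrix of within-row ranks.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
friedman_test <- function(rank_matrix) {
  r <- as.matrix(rank_matrix)
  n <- nrow(r); k <- ncol(r)
  if (n < 2L || k < 2L) stop_invalid("need at least 2 runs and 2 algorithms")
  # tie correction: sum over rows of (sum t^3 - t) over tie groups
  ties <- sum(apply(r, 1, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  }))
  denom <- n * k * (k + 1) - ties / (k - 1)
  stat <- if (denom <= 0) 0 else {
    12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
  }
  list(
    statistic = stat,
    p_value = if (denom <= 0) 1 else stats::pchisq(stat, k - 1, lower.tail = FALSE),
    df = k - 1
  )
}

#' Nemenyi critical difference
#'
#' `CD = q_alpha(k) * sqrt(k (k + 1) / (6 n))` where `q_alpha(k)` is the
#' upper-alpha studentized-range quantile at infinite degrees of freedom
#' divided by `sqrt(2)`. Two mean ranks farther apart than CD differ
#' significantly at level alpha.
#'
#' @param k Number of algorithms (2..20).
#' @param n Number of repeated measurements (>= 2).
#' @param alpha Significance level, 0.05 or 0.10.
#' @return Critical difference (positive scalar).
#' @examples
#' nemenyi_cd(7, 10)  # 2.848
#' @export
nemenyi_cd <- function(k, n, alpha = 0.05) {
  if (k < 2 || k > 20) stop_invalid("k must be in 2..20")
  if (n < 2) stop_invalid("n must be >= 2")
  if (!isTRUE(all.equal(alpha, 0.05)) && !isTRUE(all.equal(alpha, 0.10))) {
    stop_invalid("alpha must be 0.05 or 0.10")
  }
  q <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  q * sqrt(k * (k + 1) / (6 * n))
}

#' Friedman-Nemenyi rank analysis of one evaluation measure
#'
#' Ranks the algorithms within every CV run (rank 1 = best, i.e. the highest
#' metric value; ties get average ranks), runs the tie-corrected Friedman
#' test, computes the Nemenyi critical difference, and groups algorithms
#' whose mean-rank difference is below CD (data for a critical-difference
#' plot).
#'
#' @param results A `run_results` from [run_cv()].
#' @param measure One of the seven measure ids (see `measure_names()`):
#'   `auc`, `fmax_high`, `pmax_high`, `rmax_high`, `fmax_lower`,
#'   `pmax_lower`, `rmax_lower`.
#' @param alpha Significance level for the critical difference.
#' @return A `rank_analysis` object with `measure`, `rank_matrix`,
#'   `mean_ranks`, `friedman_statistic`, `friedman_p`, `nemenyi_cd`,
#'   `groups` (list of algorithm-id vectors) and `top_group`.
#' @export
rank_analysis <- function(results, measure, alpha = 0.05) {
  measure <- match.arg(measure, measure_names())
  m <- results$metrics
  wide <- matrix(NA_real_, results$runs, length(results$algorithms),
                 dimnames = list(NULL, results$algorithms))
  for (i in seq_len(nrow(m))) wide[m$run[i], m$algorithm[i]] <- m[[measure]][i]
  if (anyNA(wide)) stop_invalid("incomplete results for measure ", measure)
  rank_matrix <- t(apply(wide, 1, function(row) rank(-row)))
  mean_ranks <- colMeans(rank_matrix)
  ft <- friedman_test(rank_matrix)
  cd <- nemenyi_cd(ncol(wide), nrow(wide), alpha)
  groups <- cd_groups(mean_ranks, cd)
  top <- names(mean_ranks)[mean_ranks - min(mean_ranks) < cd]
  structure(
    list(
      measure = measure, rank_matrix = rank_matrix, mean_ranks = mean_ranks,
      friedman_statistic = ft$statistic, friedman_p = ft$p_value,
      nemenyi_cd = cd, groups = groups, top_group = top, alpha = alpha
    ),
    class = "rank_analysis"
  )
}

# Maximal sets of mutually indistinguishable algorithms for the CD plot:
# sliding window over sorted mean ranks, nested segments dropped.
cd_groups <- function(mean_ranks, cd) {
  ord <- order(mean_ranks)
  sorted <- mean_ranks[ord]
  segs <- lapply(seq_along(sorted), function(i) {
    j <- max(which(sorted - sorted[i] < cd))
    i:j
  })
  keep <- !vapply(seq_along(segs), function(i) {
    any(vapply(segs[-i], function(s) all(segs[[i]] %in% s), logical(1)))
  }, logical(1))
  lapply(segs[keep], function(s) names(sorted)[s])
}

#' Select the best algorithm across all seven measures
#'
#' An algorithm qualifies when it belongs to the top statistical group (mean
#' rank within one critical difference of the best) for *every* measure;
#' among qualifiers the one with the lowest grand mean rank wins. If no
#' algorithm is in every top group, the lowest grand mean rank wins outright
#' and the fallback is recorded.
#'
#' @param analyses List of [rank_analysis()] objects, one per measure.
#' @return List with `algorithm`, `grand_mean_ranks`, `in_all_top_groups`,
#'   `fallback`.
#' @export
select_best <- function(analyses) {
  stopifnot(length(analyses) >= 1L)
  algos <- names(analyses[[1]]$mean_ranks)
  grand <- rowMeans(vapply(analyses, function(a) a$mean_ranks[algos],
                           numeric(length(algos))))
  in_all <- algos[vapply(algos, function(a) {
    all(vapply(analyses, function(an) a %in% an$top_group, logical(1)))
  }, logical(1))]
  fallback <- length(in_all) == 0L
  pool <- if (fallback) algos else in_all
  best <- pool[which.min(grand[pool])]
  list(
    algorithm = best, grand_mean_ranks = grand,
    in_all_top_groups = in_all, fallback = fallback
  )
}

#' Two-sided Wilcoxon signed-rank test for paired metrics
#'
#' Zero differences are dropped first. With 5..25 remaining pairs the exact
#' two-sided p-value is computed by enumerating the distribution of the
#' signed-rank sum over all sign assignments (a convolution over the tied
#' average ranks, so ties are handled exactly); beyond 25 pairs the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param a,b Equal-length paired metric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("a and b must have equal length")
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop_invalid("all differences are zero; test undefined")
  if (n < 5L) stop_invalid("need at least 5 nonzero differences")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null distribution of W = sum of positively signed ranks; average
    # ranks are half-integers, so work in doubled units
    wts <- as.integer(round(2 * r))
    dist <- 1
    for (wt in wts) {
      dist <- (c(dist, numeric(wt)) + c(numeric(wt), dist)) / 2
    }
    wobs <- as.integer(round(2 * w))
    p_le <- sum(dist[seq_len(wobs + 1L)])
    p_ge <- sum(dist[(wobs + 1L):length(dist)])
    min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Paired with/without-oversampling comparison
#'
#' Runs the identical cross-validation twice — once with random oversampling
#' of the training folds, once without, sharing fold seeds so the fold
#' assignments coincide — pairs the per-run measures, and applies the
#' Wilcoxon signed-rank test per algorithm and measure.
#'
#' @inheritParams run_cv
#' @return List with the two `run_results` (`with_os`, `without_os`) and a
#'   long data.frame `tests` of `algorithm`, `measure`, `mean_with`,
#'   `mean_without`, `p_value` (NA when the test is undefined).
#' @export
compare_oversampling <- function(specs, table, runs = 10L, folds = 5L,
                                 base_seed = 1L) {
  with_os <- run_cv(specs, table, runs, folds, base_seed, oversample = TRUE)
  without_os <- run_cv(specs, table, runs, folds, base_seed, oversample = FALSE)
  rows <- list()
  for (a in with_os$algorithms) {
    for (msr in measure_names()) {
      va <- with_os$metrics[with_os$metrics$algorithm == a, ]
      vb <- without_os$metrics[without_os$metrics$algorithm == a, ]
      va <- va[order(va$run), msr]
      vb <- vb[order(vb$run), msr]
      p <- tryCatch(wilcoxon_signed_rank(vb, va), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = a, measure = msr,
        mean_with = mean(va), mean_without = mean(vb), p_value = p,
        stringsAsFactors = FALSE
      )
    }
  }
  list(with_os = with_os, without_os = without_os,
       tests = do.call(rbind, rows))
}
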