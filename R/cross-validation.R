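#' Random oversampling of the minority class
#'
#' Keeps every original row and appends minority-class rows sampled with
#' replacement until the class counts are equal; the result order is then
#' shuffled deterministically by the seed. No synthetic rows are created —
#' every appended row is an exact copy of an input minority row.
#'
#' @param table Feature table with a `label` column holding both classes.
#' @param seed Integer seed.
#' @return Balanced feature table.
#' @export
random_oversample <- function(table, seed) {
  y <- as_risk_factor(table$label)
  counts <- table(y)
  if (any(counts == 0L)) stop_invalid("both classes must be present")
  minority <- names(counts)[which.min(counts)]
  extra_n <- max(counts) - min(counts)
  with_seed(derive_seed(seed, 17L), {
    extra <- if (extra_n > 0) {
      sample(which(y == minority), extra_n, replace = TRUE)
    } else integer(0)
    out <- table[c(seq_len(nrow(table)), extra), , drop = FALSE]
    out <- out[sample(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Stratified fold assignment
#'
#' Partitions samples into `folds` folds so that per-class fold sizes differ
#' by at most one; deterministic given the seed.
#'
#' @param labels Class vector.
#' @param folds Number of folds (must not exceed the minority-class count).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:folds`.
#' @export
make_folds <- function(labels, folds, seed) {
  y <- as_risk_factor(labels)
  if (folds < 2L) stop_invalid("folds must be >= 2")
  if (folds > min(table(y))) {
    stop_invalid("folds exceeds the minority-class count; stratification impossible")
  }
  folds <- as.integer(folds)
  with_seed(derive_seed(seed, 43L), {
    f <- integer(length(y))
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      # rotate the fold order per class so remainders spread across folds
      start <- sample(folds, 1L)
      f[idx] <- ((start - 1L + seq_along(idx) - 1L) %% folds) + 1L
    }
    f
  })
}

#' Oversampled repeated stratified cross-validation of several learners
#'
#' For each of `runs` repetitions: draw fresh stratified folds; for each
#' fold, oversample the training folds only (the held-out fold is never
#' resampled or copied), fit every learner, and score the held-out fold.
#' Per (algorithm, run) the out-of-fold predictions cover every development
#' sample exactly once and are evaluated with all seven measures.
#'
#' @param specs Named list of [learner_spec()]s (names default to the
#'   algorithm ids).
#' @param table Development feature table.
#' @param runs,folds Repetition and fold counts (defaults 10 and 5).
#' @param base_seed Master seed; per-run/fold/learner sub-seeds derive from
#'   it.
#' @param oversample Apply random oversampling to the training folds
#'   (default `TRUE`).
#' @return A `run_results` object: `metrics` (long data.frame of the seven
#'   measures plus the high-class `threshold_star` per algorithm x run),
#'   `predictions` (nested list of [prediction_set()]s), and provenance.
#' @export
run_cv <- function(specs, table, runs = 10L, folds = 5L, base_seed = 1L,
                   oversample = TRUE) {
  if (inherits(specs, "learner_spec")) specs <- list(specs)
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- vapply(specs, function(s) s$algorithm, character(1))
  }
  y <- as_risk_factor(table$label)
  ids <- if (!is.null(table$patient_id)) table$patient_id else
    as.character(seq_len(nrow(table)))
  metrics <- list()
  predictions <- stats::setNames(
    replicate(length(specs), vector("list", runs), simplify = FALSE),
    names(specs)
  )
  fold_ids <- matrix(0L, nrow(table), runs)
  for (r in seq_len(runs)) {
    run_seed <- derive_seed(base_seed, r)
    f <- make_folds(y, folds, run_seed)
    fold_ids[, r] <- f
    scores <- matrix(NA_real_, nrow(table), length(specs),
                     dimnames = list(NULL, names(specs)))
    for (k in seq_len(folds)) {
      train <- table[f != k, , drop = FALSE]
      if (oversample) {
        train <- random_oversample(train, derive_seed(run_seed, k))
      }
      test <- table[f == k, , drop = FALSE]
      for (a in seq_along(specs)) {
        spec <- specs[[a]]
        spec$seed <- derive_seed(base_seed, r, k, a)
        fitted <- try(fit_learner(spec, train), silent = TRUE)
        if (inherits(fitted, "try-error")) next   # recorded as NA cell
        scores[f == k, a] <- score(fitted, test)
      }
    }
    for (a in names(specs)) {
      if (anyNA(scores[, a])) next
      ps <- prediction_set(scores[, a], y, ids)
      predictions[[a]][[r]] <- ps
      ev <- evaluate(ps)
      metrics[[length(metrics) + 1L]] <- data.frame(
        algorithm = a, run = r, t(flatten_eval(ev)),
        threshold_star = ev$high_class$threshold_star,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(
      metrics = do.call(rbind, metrics),
      predictions = predictions,
      fold_ids = fold_ids,
      base_seed = base_seed, runs = runs, folds = folds,
      oversample = oversample,
      algorithms = names(specs), specs = specs,
      sample_ids = ids
    ),
    class = "run_results"
  )
}
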