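#' Default learner set: the seven benchmark algorithms
#'
#' @param seed Base seed stored in each spec (per-fit sub-seeds are derived
#'   during cross-validation).
#' @return Named list of seven [learner_spec()]s.
#' @export
default_learners <- function(seed = 1L) {
  stats::setNames(
    lapply(ALGORITHMS, learner_spec, seed = seed),
    ALGORITHMS
  )
}

#' Run the full risk-stratification pipeline
#'
#' Chains every stage on synthetic cohorts: cohort generation (images +
#' feature extraction, or the image-free feature shortcut), oversampled
#' repeated cross-validation of the candidate learners, Friedman-Nemenyi
#' rank analysis over the seven measures, selection of the best algorithm,
#' final training with the averaged maximum-F threshold, and independent
#' validation against the ordinal-score comparator, the label-permutation
#' null and the paired bootstrap comparison.
#'
#' @param dev_spec,val_spec [cohort_spec()]s for the development and
#'   validation cohorts.
#' @param learners Named list of [learner_spec()]s (default all seven).
#' @param runs,folds Cross-validation repetitions and folds.
#' @param seed Master seed for the CV/validation stages.
#' @param use_images If `TRUE` synthesize images and extract texture
#'   features; otherwise draw feature tables directly.
#' @param n_informative Informative feature count for the feature shortcut.
#' @param force_algorithm Skip rank-based selection and use this algorithm id
#'   (e.g. `"QSVM"`); `NULL` (default) selects by rank analysis.
#' @param replicates Permutation and bootstrap replicate count.
#' @return List with the feature tables, `cv` results, `analyses`,
#'   `selection`, `final` classifier, and `validation` (report plus
#'   components).
#' @export
run_pipeline <- function(dev_spec, val_spec, learners = default_learners(),
                         runs = 10L, folds = 5L, seed = 1L,
                         use_images = TRUE, n_informative = 20L,
                         force_algorithm = NULL, replicates = 100L) {
  make_table <- function(spec, prefix) {
    if (use_images) {
      extract_cohort(generate_cohort(spec, id_prefix = prefix))
    } else {
      tab <- generate_feature_table(spec, n_informative = n_informative)
      tab$patient_id <- paste0(prefix, tab$patient_id)
      tab
    }
  }
  dev <- make_table(dev_spec, "D")
  val <- make_table(val_spec, "V")

  cv <- run_cv(learners, dev, runs = runs, folds = folds, base_seed = seed)
  analyses <- NULL
  if (is.null(force_algorithm)) {
    analyses <- lapply(measure_names(), function(msr) rank_analysis(cv, msr))
    names(analyses) <- measure_names()
    selection <- select_best(analyses)
  } else {
    selection <- list(algorithm = force_algorithm, fallback = FALSE,
                      forced = TRUE)
  }
  final <- train_final(learner_spec(selection$algorithm,
                                    seed = derive_seed(seed, 499L)),
                       dev, cv)

  applied <- apply_classifier(final, val)
  cls_measures <- thresholded_measures(applied$predictions$scores,
                                       val$label, final$threshold)
  cmp_measures <- pirads_evaluate(val$pirads, val$label)
  perm <- permutation_benchmark(final, val, replicates = replicates,
                                seed = derive_seed(seed, 601L))
  comp <- bootstrap_compare(applied$predictions$scores, final$threshold,
                            val$pirads, val$label, replicates = replicates,
                            seed = derive_seed(seed, 613L))
  report <- build_report(cls_measures, cmp_measures, perm, comp)

  list(
    dev = dev, val = val, cv = cv, analyses = analyses,
    selection = selection, final = final,
    validation = list(
      applied = applied, classifier = cls_measures, comparator = cmp_measures,
      permutation = perm, comparison = comp, report = report
    )
  )
}
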