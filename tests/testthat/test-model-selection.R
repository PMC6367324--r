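test_that("random oversampling balances classes with copies only", {
  tab <- small_shift_table(n_high = 14, n_lower = 54, seed = 2)
  os <- random_oversample(tab, seed = 3)
  expect_identical(nrow(os), 108L)
  expect_identical(unname(table(os$label)["high"]), 54L)
  # every minority row is a copy of an input minority row
  key <- function(t) unname(apply(t[, feature_manifest()], 1, paste, collapse = "|"))
  expect_true(all(key(os[os$label == "high", ]) %in%
                    key(tab[tab$label == "high", ])))
  # majority rows untouched as a multiset
  expect_identical(sort(key(os[os$label == "lower", ])),
                   sort(key(tab[tab$label == "lower", ])))

  balanced <- small_shift_table(n_high = 10, n_lower = 10, seed = 4)
  os2 <- random_oversample(balanced, seed = 5)
  expect_identical(sort(os2$patient_id), sort(balanced$patient_id))
})

test_that("stratified folds partition each class within one sample", {
  labs <- rep(c("lower", "high"), c(40, 10))
  f <- make_folds(labs, 5, seed = 1)
  expect_identical(sort(unique(f)), 1:5)
  for (k in 1:5) {
    expect_identical(sum(f == k & labs == "lower"), 8L)
    expect_identical(sum(f == k & labs == "high"), 2L)
  }

  labs2 <- rep(c("lower", "high"), c(54, 14))
  f2 <- make_folds(labs2, 5, seed = 2)
  hi_counts <- vapply(1:5, function(k) sum(f2 == k & labs2 == "high"), integer(1))
  expect_true(all(hi_counts %in% 2:3))
  expect_identical(sum(hi_counts), 14L)
  expect_identical(make_folds(labs2, 5, seed = 2), f2)

  expect_error(make_folds(rep(c("lower", "high"), c(20, 3)), 5, 1),
               "minority")
})

test_that("cross-validation covers every sample exactly once per run", {
  tab <- small_shift_table(n_high = 8, n_lower = 20, effect = 1, seed = 6)
  cv <- run_cv(list(LSVM = learner_spec("LSVM"), LDA = learner_spec("LDA")),
               tab, runs = 3, folds = 4, base_seed = 9)
  for (a in cv$algorithms) {
    for (r in 1:3) {
      ps <- cv$predictions[[a]][[r]]
      expect_identical(sort(ps$sample_ids), sort(tab$patient_id))
      expect_length(ps$scores, nrow(tab))
    }
  }
  expect_identical(nrow(cv$metrics), 6L)
  # determinism of the whole procedure
  cv2 <- run_cv(list(LSVM = learner_spec("LSVM"), LDA = learner_spec("LDA")),
                tab, runs = 3, folds = 4, base_seed = 9)
  expect_equal(cv$metrics, cv2$metrics)
})

test_that("Friedman statistic honors ties, degeneracy and the k=2 identity", {
  # identical columns: every row ties completely
  same <- matrix(rep(c(1.5, 1.5), 10), 10, 2)
  ft <- friedman_test(same)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p_value, 1)

  # one algorithm always best among 7 over 10 runs is significant
  set.seed(1)
  vals <- matrix(runif(70), 10, 7)
  vals[, 3] <- vals[, 3] + 10
  ranks <- t(apply(vals, 1, function(r) rank(-r)))
  expect_lt(friedman_test(ranks)$p_value, 0.05)

  # k = 2, tie-free: statistic equals (2w - n)^2 / n exactly, and p matches
  # the normal-approximation sign test
  for (s in 1:25) {
    set.seed(s)
    n <- 30
    a <- runif(n); b <- runif(n)
    rk <- t(apply(cbind(a, b), 1, function(x) rank(-x)))
    ft <- friedman_test(rk)
    w <- sum(a > b)
    expect_equal(ft$statistic, (2 * w - n)^2 / n, tolerance = 1e-12)
    expect_equal(ft$p_value, stats::pchisq((2 * w - n)^2 / n, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }

  # cross-check the tie-corrected statistic against stats::friedman.test
  for (s in 1:20) {
    set.seed(100 + s)
    y <- matrix(sample(1:5, 8 * 4, replace = TRUE), 8, 4)  # many ties
    rk <- t(apply(y, 1, rank))
    ours <- friedman_test(rk)
    ref <- stats::friedman.test(y)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Nemenyi critical difference matches the studentized-range form", {
  expect_lt(abs(nemenyi_cd(7, 10, 0.05) - 2.849), 0.001)
  for (n in c(5, 10, 20)) {
    expect_equal(nemenyi_cd(2, n, 0.05), 1.959964 / sqrt(n), tolerance = 1e-4)
  }
  cds <- vapply(2:30, function(n) nemenyi_cd(7, n), numeric(1))
  expect_true(all(diff(cds) < 0))
  expect_error(nemenyi_cd(25, 10), "k")
  expect_error(nemenyi_cd(7, 10, alpha = 0.01), "alpha")
})

test_that("rank analysis produces valid rank rows and CD groups", {
  tab <- small_shift_table(n_high = 10, n_lower = 25, effect = 1.5, seed = 8)
  cv <- run_cv(default_learners(), tab, runs = 4, folds = 5, base_seed = 3)
  ra <- rank_analysis(cv, "auc")
  expect_true(all(abs(rowSums(ra$rank_matrix) - 28) < 1e-9))
  expect_gt(ra$nemenyi_cd, 0)
  expect_true(all(unlist(ra$groups) %in% cv$algorithms))

  # grouping matches a brute-force all-pairs comparison
  for (s in 1:50) {
    set.seed(200 + s)
    mr <- stats::setNames(runif(7, 1, 7), paste0("alg", 1:7))
    cd <- runif(1, 0.5, 3)
    groups <- radstrat:::cd_groups(mr, cd)
    # each group is mutually within cd
    for (g in groups) {
      expect_true(all(abs(outer(mr[g], mr[g], `-`)) < cd))
    }
    # any pair within cd lies together in some group
    for (i in 1:6) for (j in (i + 1):7) {
      if (abs(mr[i] - mr[j]) < cd) {
        in_one <- any(vapply(groups, function(g) {
          all(names(mr)[c(i, j)] %in% g)
        }, logical(1)))
        expect_true(in_one)
      }
    }
  }
})

test_that("best-algorithm selection prefers the all-measure top group", {
  tab <- small_shift_table(n_high = 10, n_lower = 25, effect = 1.5, seed = 8)
  cv <- run_cv(default_learners(), tab, runs = 4, folds = 5, base_seed = 3)
  analyses <- lapply(radstrat:::measure_names(), function(m) rank_analysis(cv, m))
  names(analyses) <- radstrat:::measure_names()
  sel1 <- select_best(analyses)
  sel2 <- select_best(analyses)
  expect_identical(sel1, sel2)
  expect_true(sel1$algorithm %in% cv$algorithms)

  # synthetic dominance: one algorithm best on every measure in every run
  dom <- cv
  dom$metrics[dom$metrics$algorithm == "LDA", radstrat:::measure_names()] <- 2
  analyses_dom <- lapply(radstrat:::measure_names(), function(m) rank_analysis(dom, m))
  expect_identical(select_best(analyses_dom)$algorithm, "LDA")
})

test_that("final training averages the per-run optimal thresholds", {
  tab <- small_shift_table(n_high = 10, n_lower = 25, effect = 1.5, seed = 10)
  cv <- run_cv(list(QSVM = learner_spec("QSVM")), tab, runs = 3, folds = 5,
               base_seed = 5)
  fin <- train_final(learner_spec("QSVM", seed = 1), tab, cv)
  thr <- cv$metrics$threshold_star[order(cv$metrics$run)]
  expect_equal(fin$threshold, mean(thr), tolerance = 1e-12)
  expect_gte(fin$threshold, min(thr))
  expect_lte(fin$threshold, max(thr))
  expect_identical(fin$threshold_provenance, thr)
  expect_error(train_final(learner_spec("RF"), tab, cv), "no runs")
})

test_that("Wilcoxon signed-rank reproduces exact and degenerate behavior", {
  a <- (1:10) / 20
  expect_equal(wilcoxon_signed_rank(a, a + 1), 2 / 1024, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(a, a), "zero")
  expect_equal(wilcoxon_signed_rank(a, a + 1), wilcoxon_signed_rank(a + 1, a))

  # agreement with stats::wilcox.test in the exact regime
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(12); y <- rnorm(12, 0.5)
    if (anyDuplicated(abs(y - x)) > 0) next   # continuous draws: no ties expected
    ref <- stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)$p.value
    expect_equal(wilcoxon_signed_rank(x, y), ref, tolerance = 1e-12)
  }
})

test_that("oversampling comparison shares folds and reports every cell", {
  tab <- small_shift_table(n_high = 8, n_lower = 20, effect = 1, seed = 13)
  cmp <- compare_oversampling(list(QSVM = learner_spec("QSVM"),
                                   LDA = learner_spec("LDA")),
                              tab, runs = 5, folds = 4, base_seed = 11)
  expect_identical(cmp$with_os$fold_ids, cmp$without_os$fold_ids)
  expect_identical(nrow(cmp$tests), 2L * 7L)
  expect_identical(sort(unique(cmp$tests$measure)), sort(radstrat:::measure_names()))
})
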