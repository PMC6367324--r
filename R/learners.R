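ALGORITHMS <- c("LogReg", "LSVM", "QSVM", "CSVM", "GSVM", "LDA", "RF")
SVM_ALGOS <- c("LSVM", "QSVM", "CSVM", "GSVM")

#' Specify one of the seven classification algorithms
#'
#' The benchmark compares logistic regression (`LogReg`), support vector
#' machines with linear, quadratic, cubic and Gaussian kernels (`LSVM`,
#' `QSVM`, `CSVM`, `GSVM`), linear discriminant analysis (`LDA`) and random
#' forest (`RF`). Hyperparameter defaults are frozen: SVM box constraint 1
#' and kernel scale `gamma = 1/p`; polynomial kernels inhomogeneous
#' (`+1` offset, switchable with `homogeneous = TRUE`); RF with 100 trees;
#' ridge-penalized logistic regression (`lambda = 1/n`); LDA with a fixed
#' Tikhonov covariance regularizer.
#'
#' @param algorithm One of `r paste(ALGORITHMS, collapse = ", ")`.
#' @param hyperparameters Named list overriding defaults (`cost`, `gamma`,
#'   `ntree`, `lambda`, `homogeneous`, `calibration_folds`).
#' @param seed Integer seed for the stochastic parts (RF bootstrap,
#'   calibration folds).
#' @return A `learner_spec` object.
#' @examples
#' learner_spec("QSVM", seed = 1)
#' @export
learner_spec <- function(algorithm, hyperparameters = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  structure(
    list(algorithm = algorithm, hyperparameters = hyperparameters,
         seed = as.integer(seed)),
    class = "learner_spec"
  )
}

hp <- function(spec, name, default) {
  v <- spec$hyperparameters[[name]]
  if (is.null(v)) default else v
}

#' Evaluate an SVM kernel
#'
#' Linear `u.v`; quadratic `(1 + g u.v)^2`; cubic `(1 + g u.v)^3` (offset
#' dropped when `homogeneous = TRUE`); Gaussian `exp(-g ||u - v||^2)`.
#' `g` defaults to `1/length(u)`.
#'
#' @param u,v Numeric vectors of equal length.
#' @param spec A [learner_spec()] for one of the SVM algorithms.
#' @return Kernel value.
#' @examples
#' kernel_value(c(1, 0), c(0, 1), learner_spec("GSVM", list(gamma = 1)))
#' @export
kernel_value <- function(u, v, spec) {
  stopifnot(inherits(spec, "learner_spec"), length(u) == length(v))
  if (!spec$algorithm %in% SVM_ALGOS) {
    stop_invalid("kernel_value applies only to SVM algorithms")
  }
  g <- hp(spec, "gamma", 1 / length(u))
  off <- if (isTRUE(hp(spec, "homogeneous", FALSE))) 0 else 1
  switch(spec$algorithm,
    LSVM = sum(u * v),
    QSVM = (off + g * sum(u * v))^2,
    CSVM = (off + g * sum(u * v))^3,
    GSVM = exp(-g * sum((u - v)^2))
  )
}

fit_standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1   # zero-variance columns kept, scale 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(std, x) {
  scale(x, center = std$center, scale = std$scale)[, , drop = FALSE]
}

fit_svm_core <- function(spec, xs, y) {
  g <- hp(spec, "gamma", 1 / ncol(xs))
  cost <- hp(spec, "cost", 1)
  off <- if (isTRUE(hp(spec, "homogeneous", FALSE))) 0 else 1
  args <- switch(spec$algorithm,
    LSVM = list(kernel = "linear"),
    QSVM = list(kernel = "polynomial", degree = 2, gamma = g, coef0 = off),
    CSVM = list(kernel = "polynomial", degree = 3, gamma = g, coef0 = off),
    GSVM = list(kernel = "radial", gamma = g)
  )
  core <- do.call(e1071::svm, c(
    list(x = xs, y = y, cost = cost, scale = FALSE, probability = FALSE),
    args
  ))
  # orient decision values so larger = more high-risk
  dv <- as.numeric(attr(stats::predict(core, xs, decision.values = TRUE),
                        "decision.values"))
  flip <- mean(dv[y == "high"]) < mean(dv[y == "lower"])
  list(core = core, flip = flip)
}

svm_decision <- function(fitobj, xs) {
  dv <- as.numeric(attr(stats::predict(fitobj$core, xs, decision.values = TRUE),
                        "decision.values"))
  if (fitobj$flip) -dv else dv
}

# Platt-style sigmoid calibration fitted on seeded stratified out-of-fold
# decision values (libsvm's built-in probability machinery is not
# reproducible across fits, so calibration is done here).
fit_platt <- function(spec, xs, y, folds = 3L) {
  n <- nrow(xs)
  dv_oof <- rep(NA_real_, n)
  assign_f <- with_seed(derive_seed(spec$seed, 211L), {
    f <- integer(n)
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
  for (k in seq_len(folds)) {
    tr <- assign_f != k
    if (all(tr) || length(unique(y[tr])) < 2L) next
    sub <- fit_svm_core(spec, xs[tr, , drop = FALSE], y[tr])
    dv_oof[!tr] <- svm_decision(sub, xs[!tr, , drop = FALSE])
  }
  use <- is.finite(dv_oof)
  full <- fit_svm_core(spec, xs, y)
  sigmoid <- function(dv, lab) {
    cal <- suppressWarnings(stats::glm(
      I(lab == "high") ~ dv, family = stats::binomial()
    ))
    unname(stats::coef(cal))
  }
  cf <- if (sum(use) < 4L || length(unique(y[use])) < 2L) c(NA_real_, NA_real_) else
    sigmoid(dv_oof[use], y[use])
  if (anyNA(cf) || cf[2] < 0) {
    # degenerate or inverted out-of-fold calibration (possible on tiny
    # training sets): fall back to the training decision values so the
    # probability map stays non-decreasing in the decision value
    cf <- sigmoid(svm_decision(full, xs), y)
    if (anyNA(cf) || cf[2] < 0) cf <- c(0, 0)
  }
  list(fit = full, a = cf[1], b = cf[2])
}

fit_shrinkage_lda <- function(xs, y, alpha = 1e-3) {
  # pooled within-class covariance with fixed Tikhonov regularization
  p <- ncol(xs)
  mus <- lapply(levels(y), function(cls) colMeans(xs[y == cls, , drop = FALSE]))
  names(mus) <- levels(y)
  centered <- xs
  for (cls in levels(y)) {
    centered[y == cls, ] <- sweep(xs[y == cls, , drop = FALSE], 2, mus[[cls]])
  }
  S <- crossprod(centered) / (nrow(xs) - 2)
  S <- S + diag(alpha * mean(diag(S)) + 1e-10, p)
  Sinv <- solve(S)
  priors <- table(y) / length(y)
  list(mus = mus, Sinv = Sinv, log_priors = log(as.numeric(priors)),
       classes = levels(y))
}

lda_scores <- function(core, xs) {
  disc <- vapply(seq_along(core$classes), function(i) {
    mu <- core$mus[[core$classes[i]]]
    drop(xs %*% (core$Sinv %*% mu)) - 0.5 * drop(mu %*% core$Sinv %*% mu) +
      core$log_priors[i]
  }, numeric(nrow(xs)))
  stats::plogis(disc[, which(core$classes == "high")] -
                  disc[, which(core$classes == "lower")])
}

#' Fit a learner to a feature table
#'
#' Standardizes every feature to zero mean / unit sd using the training rows
#' only (zero-variance features keep scale 1), fits the requested algorithm,
#' and attaches a probability map to `[0, 1]`: native probabilities for
#' LogReg, LDA and RF, and a Platt sigmoid fitted on seeded 3-fold
#' out-of-fold decision values for the margin-based SVMs. Deterministic
#' given the spec seed.
#'
#' @param spec A [learner_spec()].
#' @param table Feature table with at least two samples per class and no
#'   missing values.
#' @return A `trained_model` object; use [score()] to obtain high-risk
#'   probabilities.
#' @export
fit_learner <- function(spec, table) {
  stopifnot(inherits(spec, "learner_spec"))
  xy <- table_xy(table)
  counts <- table(xy$y)
  if (any(counts < 2L) || length(unique(xy$y)) < 2L) {
    stop_invalid("training data must contain at least 2 samples per class")
  }
  std <- fit_standardizer(xy$x)
  xs <- apply_standardizer(std, xy$x)
  core <- switch(spec$algorithm,
    LogReg = {
      lam <- hp(spec, "lambda", 1 / nrow(xs))
      suppressWarnings(glmnet::glmnet(xs, xy$y, family = "binomial", alpha = 0,
                                      lambda = lam, standardize = FALSE))
    },
    LDA = fit_shrinkage_lda(xs, xy$y, alpha = hp(spec, "lda_alpha", 1e-3)),
    RF = with_seed(derive_seed(spec$seed, 31L), {
      randomForest::randomForest(xs, xy$y, ntree = hp(spec, "ntree", 100L))
    }),
    fit_platt(spec, xs, xy$y, folds = hp(spec, "calibration_folds", 3L))
  )
  structure(
    list(spec = spec, standardizer = std, core = core,
         feature_names = xy$feature_names),
    class = "trained_model"
  )
}

#' Score samples with a trained model
#'
#' @param model A `trained_model` from [fit_learner()].
#' @param table Feature table whose feature columns match the model's
#'   training manifest exactly (names and order).
#' @return Numeric vector of high-risk probabilities in `[0, 1]`, one per
#'   row, in input order.
#' @export
score <- function(model, table) {
  stopifnot(inherits(model, "trained_model"))
  feats <- if (is.data.frame(table)) {
    setdiff(names(table), c("patient_id", "label", "pirads"))
  } else colnames(table)
  if (!identical(feats, model$feature_names)) {
    stop_invalid("feature names/order mismatch the model's training manifest")
  }
  x <- as.matrix(if (is.data.frame(table)) table[, feats, drop = FALSE] else table)
  storage.mode(x) <- "double"
  xs <- apply_standardizer(model$standardizer, x)
  alg <- model$spec$algorithm
  p <- switch(alg,
    LogReg = as.numeric(stats::predict(model$core, newx = xs, type = "response")),
    LDA = lda_scores(model$core, xs),
    RF = stats::predict(model$core, xs, type = "prob")[, "high"],
    stats::plogis(model$core$a + model$core$b * svm_decision(model$core$fit, xs))
  )
  unname(pmin(1, pmax(0, p)))
}

#' Save / load a trained model
#'
#' Persists a model as a directory with versioned JSON metadata (algorithm,
#' hyperparameters, seed, feature manifest, calibration coefficients) plus an
#' RDS file for the fitted core state.
#'
#' @param model A `trained_model`.
#' @param dir Target directory.
#' @return `save_model` returns `dir` invisibly; `load_model` the restored
#'   model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format_version = 1L,
    algorithm = model$spec$algorithm,
    hyperparameters = model$spec$hyperparameters,
    seed = model$spec$seed,
    feature_names = model$feature_names,
    calibration = if (model$spec$algorithm %in% SVM_ALGOS) {
      list(a = model$core$a, b = model$core$b)
    } else NULL
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  model <- readRDS(file.path(dir, "model.rds"))
  stopifnot(inherits(model, "trained_model"))
  model
}
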