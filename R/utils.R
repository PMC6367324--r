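#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation. Mixes a base seed with integer context
# values (patient index, CV run, fold, learner index, ...) so that every
# stochastic unit of the pipeline owns an independent, reproducible stream and
# cohorts are extensible without perturbing earlier patients. Arithmetic is
# done in doubles (exact below 2^53) and reduced mod 2^31 - 1 to stay a valid
# R integer seed.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + (as.numeric(p) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

# with_seed: evaluate expr under a local RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Risk-class factor levels
#'
#' The two risk classes used throughout the package. `"high"` is always the
#' minority / positive class of interest; `"lower"` the majority class.
#'
#' @return Character vector `c("lower", "high")`.
#' @export
risk_levels <- function() c("lower", "high")

as_risk_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), risk_levels())
  if (length(bad)) {
    stop_invalid("unknown risk label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = risk_levels())
}
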