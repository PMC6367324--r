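#' Specification of a synthetic two-class cohort
#'
#' Bundles everything that determines a synthetic cohort: class sizes, image
#' geometry, per-class/per-modality texture parameters, the between-class
#' separation multiplier, reader-score noise and the master seed. The same
#' spec and seed always reproduce the identical cohort bit for bit.
#'
#' The default texture parameters emulate the qualitative structure of
#' paired-modality prostate MRI regions of interest: the ADC-like modality of
#' the high-risk class has a *lower* mean intensity (restricted diffusion in
#' aggressive tumours), while the T2W-like modality differs in texture
#' correlation length. `effect_size` scales both between-class differences;
#' 0 makes the classes generatively identical. Per-patient jitter of the mean
#' intensity and correlation length supplies realistic between-patient
#' variance so that patient-level features are not trivially separable.
#'
#' @param n_high,n_lower Number of high-risk / lower-risk patients.
#' @param image_size Pixels per side of the square ROI grid (>= 16).
#' @param effect_size Dimensionless multiplier of the between-class parameter
#'   differences (>= 0); 0 gives a null cohort.
#' @param texture_params Nested list `list(t2w = ..., adc = ...)`; each
#'   modality has `mean_intensity`, `intensity_sd`, `correlation_length`
#'   (pixels), the per-unit-effect class deltas `delta_mean`, `delta_corr`
#'   applied to the high-risk class, and per-patient jitter sds `jitter_mean`,
#'   `jitter_corr` (lognormal sd for the correlation length).
#' @param reader_noise_sd Sd of the latent ordinal reader-score noise.
#' @param seed Master seed; expanded into per-patient sub-seeds by a counter
#'   scheme, so enlarging the cohort never perturbs earlier patients.
#'
#' @return A `cohort_spec` object.
#' @examples
#' spec <- cohort_spec(n_high = 14, n_lower = 54, seed = 1)
#' @export
cohort_spec <- function(n_high, n_lower, image_size = 48L, effect_size = 1,
                        texture_params = default_texture_params(),
                        reader_noise_sd = 0.6, seed = 1L) {
  if (n_high < 0 || n_lower < 0 || n_high + n_lower < 1) {
    stop_invalid("need n_high >= 0, n_lower >= 0 and at least one patient")
  }
  if (image_size < 16) stop_invalid("image_size must be >= 16")
  if (effect_size < 0) stop_invalid("effect_size must be >= 0")
  if (reader_noise_sd < 0) stop_invalid("reader_noise_sd must be >= 0")
  for (mod in c("t2w", "adc")) {
    tp <- texture_params[[mod]]
    if (is.null(tp)) stop_invalid("texture_params must have t2w and adc entries")
    if (tp$correlation_length <= 0) stop_invalid("correlation_length must be > 0")
    if (tp$intensity_sd < 0) stop_invalid("intensity_sd must be >= 0")
  }
  structure(
    list(
      n_high = as.integer(n_high), n_lower = as.integer(n_lower),
      image_size = as.integer(image_size), effect_size = effect_size,
      texture_params = texture_params, reader_noise_sd = reader_noise_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Default per-modality texture parameters
#'
#' @return Nested list with `t2w` and `adc` parameter sets (see
#'   [cohort_spec()]).
#' @export
default_texture_params <- function() {
  list(
    t2w = list(
      mean_intensity = 600, intensity_sd = 120, correlation_length = 2.5,
      delta_mean = 0, delta_corr = 1.0,
      jitter_mean = 60, jitter_corr = 0.10
    ),
    adc = list(
      mean_intensity = 1200, intensity_sd = 180, correlation_length = 2.0,
      delta_mean = -150, delta_corr = 0,
      jitter_mean = 100, jitter_corr = 0.10
    )
  )
}

#' Generate one stationary correlated-texture ROI image
#'
#' Draws a Gaussian random field by frequency-domain filtering of white noise
#' with a Gaussian spectral envelope whose width is set by the correlation
#' length, affine-scales it to the requested mean and sd, clips at zero,
#' rounds to integer intensities (lossless 16-bit storage), and attaches an
#' elliptical in-ROI mask with semi-axes drawn uniformly between 0.5 and 0.9
#' of the half-size.
#'
#' @param class_params List with `mean_intensity`, `intensity_sd` and
#'   `correlation_length` (pixels, > 0).
#' @param image_size Pixels per side (>= 16).
#' @param seed Integer seed; same seed and parameters give a pixel-identical
#'   image.
#'
#' @return A [roi_image()].
#' @export
synth_texture_image <- function(class_params, image_size, seed) {
  if (image_size < 16) stop_invalid("image_size must be >= 16")
  ell <- class_params$correlation_length
  if (!is.finite(ell) || ell <= 0) stop_invalid("correlation_length must be > 0")
  if (class_params$intensity_sd < 0) stop_invalid("intensity_sd must be >= 0")
  n <- as.integer(image_size)
  with_seed(seed, {
    # elliptical mask, semi-axes in [0.5, 0.9] of the half-size
    ax <- stats::runif(2, 0.5, 0.9) * n / 2
    ctr <- (n + 1) / 2
    yy <- matrix(seq_len(n) - ctr, n, n)
    xx <- t(yy)
    mask <- (yy / ax[1])^2 + (xx / ax[2])^2 <= 1

    z <- matrix(stats::rnorm(n * n), n, n)
    f <- sqrt(outer(fft_freqs(n)^2, fft_freqs(n)^2, `+`))
    env <- exp(-(pi * ell * f)^2)
    field <- Re(stats::fft(stats::fft(z) * env, inverse = TRUE)) / (n * n)
    s <- stats::sd(as.vector(field))
    if (s > 0) field <- (field - mean(field)) / s
    img <- class_params$mean_intensity + class_params$intensity_sd * field
    img <- round(pmin(pmax(img, 0), 65535))
    roi_image(img, mask)
  })
}

#' Simulate an ordinal reader score
#'
#' Draws a 1-5 suspicion score from a latent Gaussian: class mean (defaults
#' 4.3 for high risk, 3.3 for lower risk) plus noise, rounded and clipped to
#' the ordinal range.
#'
#' @param label Risk class, `"high"` or `"lower"`.
#' @param reader_noise_sd Latent noise sd (>= 0).
#' @param seed Integer seed.
#' @param class_means Named latent means, default `c(lower = 3.3, high = 4.3)`.
#'
#' @return Integer score in 1..5.
#' @export
simulate_pirads <- function(label, reader_noise_sd, seed,
                            class_means = c(lower = 3.3, high = 4.3)) {
  if (reader_noise_sd < 0) stop_invalid("reader_noise_sd must be >= 0")
  label <- match.arg(as.character(label), risk_levels())
  with_seed(seed, {
    latent <- class_means[[label]] + stats::rnorm(1, 0, reader_noise_sd)
    as.integer(pmin(5, pmax(1, round(latent))))
  })
}

# Per-patient generative parameters: class effect + patient jitter.
patient_params <- function(spec, modality, label, seed) {
  tp <- spec$texture_params[[modality]]
  eff <- if (label == "high") spec$effect_size else 0
  with_seed(seed, {
    mean_i <- tp$mean_intensity + eff * tp$delta_mean +
      stats::rnorm(1, 0, tp$jitter_mean)
    corr <- (tp$correlation_length + eff * tp$delta_corr) *
      exp(stats::rnorm(1, 0, tp$jitter_corr))
    list(
      mean_intensity = max(mean_i, 1),
      intensity_sd = tp$intensity_sd,
      correlation_length = corr
    )
  })
}

#' Generate a synthetic cohort of paired-modality patients
#'
#' Produces exactly `n_high + n_lower` patients. Each patient gets a T2W-like
#' and an ADC-like ROI image drawn with class- and modality-specific
#' parameters (plus per-patient jitter), a risk label, and an ordinal reader
#' score correlated with the label. With `effect_size = 0` the two classes
#' are generatively identical.
#'
#' @param spec A [cohort_spec()].
#' @param id_prefix Prefix for patient identifiers.
#' @return List of patients; each has `patient_id`, `t2w`, `adc`, `label`,
#'   `pirads`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_high = 2, n_lower = 3, seed = 7))
#' length(cohort)
#' @export
generate_cohort <- function(spec, id_prefix = "P") {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- c(rep("high", spec$n_high), rep("lower", spec$n_lower))
  lapply(seq_along(labels), function(i) {
    lab <- labels[i]
    t2w <- synth_texture_image(
      patient_params(spec, "t2w", lab, derive_seed(spec$seed, i, 1L)),
      spec$image_size, derive_seed(spec$seed, i, 2L)
    )
    adc <- synth_texture_image(
      patient_params(spec, "adc", lab, derive_seed(spec$seed, i, 3L)),
      spec$image_size, derive_seed(spec$seed, i, 4L)
    )
    # the two modalities depict the same registered ROI: share the t2w mask
    adc <- roi_image(adc$intensities, t2w$mask)
    list(
      patient_id = sprintf("%s%03d", id_prefix, i),
      t2w = t2w,
      adc = adc,
      label = lab,
      pirads = simulate_pirads(lab, spec$reader_noise_sd,
                               derive_seed(spec$seed, i, 5L))
    )
  })
}

#' Generate a synthetic feature table directly (image-free shortcut)
#'
#' Draws the 110-dimensional feature vectors from a correlated Gaussian model
#' without synthesizing images, so classifier-side modules can be tested
#' cheaply. Features are equicorrelated in blocks of 11 (rho = 0.3, one
#' latent factor per block). Under `structure = "shift"`, `n_informative`
#' evenly spaced features get a class-mean shift of `effect_size` within-class
#' sds. Under `structure = "xor"`, the informative features split into two
#' halves loading (with strength `effect_size`) on two latent signs whose
#' product encodes the class, so no single feature carries marginal signal
#' and only interaction-capable learners can separate the classes.
#'
#' @param spec A [cohort_spec()] (image parameters are ignored).
#' @param n_informative Number of informative features (0..110).
#' @param structure `"shift"` (default) or `"xor"`.
#' @return A `data.frame`: `patient_id`, 110 manifest-named feature columns,
#'   `label`, `pirads`.
#' @export
generate_feature_table <- function(spec, n_informative = 20L,
                                   structure = c("shift", "xor")) {
  stopifnot(inherits(spec, "cohort_spec"))
  structure <- match.arg(structure)
  p <- 110L
  if (n_informative > p || n_informative < 0) {
    stop_invalid("n_informative must be between 0 and 110")
  }
  n <- spec$n_high + spec$n_lower
  labels <- c(rep("high", spec$n_high), rep("lower", spec$n_lower))
  rho <- 0.3
  block <- rep(seq_len(10), each = 11L)
  info <- if (n_informative > 0) {
    unique(round(seq(1, p, length.out = n_informative)))
  } else integer(0)

  with_seed(derive_seed(spec$seed, 97L), {
    zb <- matrix(stats::rnorm(n * 10), n, 10)        # block factors
    eps <- matrix(stats::rnorm(n * p), n, p)
    x <- sqrt(rho) * zb[, block] + sqrt(1 - rho) * eps
    if (length(info) > 0 && spec$effect_size > 0) {
      if (structure == "shift") {
        x[labels == "high", info] <- x[labels == "high", info] + spec$effect_size
      } else {
        s1 <- sample(c(-1, 1), n, replace = TRUE)
        s2 <- s1 * ifelse(labels == "high", 1, -1)
        half <- seq_len(floor(length(info) / 2))
        x[, info[half]] <- x[, info[half]] + spec$effect_size * s1
        x[, info[-half]] <- x[, info[-half]] + spec$effect_size * s2
      }
    }
    colnames(x) <- feature_manifest()
    tab <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      x, check.names = FALSE, stringsAsFactors = FALSE
    )
    tab$label <- as_risk_factor(labels)
    tab$pirads <- vapply(
      seq_len(n),
      function(i) simulate_pirads(labels[i], spec$reader_noise_sd,
                                  derive_seed(spec$seed, i, 5L)),
      integer(1)
    )
    tab
  })
}
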