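const_roi <- function(value = 5, n = 8) {
  roi_image(matrix(value, n, n), matrix(TRUE, n, n))
}

test_that("quantization follows the min-max binning contract", {
  expect_true(all(quantize(const_roi(), 8)[matrix(TRUE, 8, 8)] == 0))

  vals <- matrix(rep(c(0, 1, 2, 3), 16), 8, 8)
  q <- quantize(roi_image(vals), 4)
  expect_identical(as.integer(q), as.integer(vals))

  set.seed(3)
  big <- roi_image(matrix(runif(10000, 0, 100), 100, 100))
  q <- quantize(big, 16)
  freq <- tabulate(q + 1L, 16) / 10000
  expect_true(all(abs(freq - 1 / 16) < 0.01))

  expect_error(quantize(big, 1), "levels")
})

test_that("histogram features match closed-form values on degenerate cases", {
  h <- histogram_features(const_roi(5))
  expect_equal(h[["hist_mean"]], 5)
  expect_equal(h[["hist_sd"]], 0)
  expect_equal(h[["hist_range"]], 0)
  expect_equal(h[["hist_entropy"]], 0)
  expect_equal(h[["hist_uniformity"]], 1)
  expect_equal(h[["hist_skewness"]], 0)
  expect_equal(h[["hist_kurtosis"]], 0)

  two <- roi_image(matrix(rep(c(0, 100), each = 32), 8, 8))
  h2 <- histogram_features(two)
  expect_equal(h2[["hist_entropy"]], 1)
  expect_equal(h2[["hist_uniformity"]], 0.5)
  expect_equal(h2[["hist_mean"]], 50)
  expect_equal(h2[["hist_median"]], 50)

  sym <- roi_image(matrix(c(1:32, 32:1), 8, 8))
  expect_lt(abs(histogram_features(sym)[["hist_skewness"]]), 1e-6)
})

test_that("GLCM construction matches hand enumeration and its invariants", {
  # quantized rows [[0,1],[0,1]]
  q <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  attr(q, "levels") <- 2L
  g <- compute_glcm(q, c(0, 1))
  expect_equal(g$probabilities,
               matrix(c(0, 0.5, 0.5, 0), 2, 2))

  gc <- compute_glcm(quantize(const_roi(), 8), c(0, 1))
  expect_equal(gc$probabilities[1, 1], 1)
  expect_equal(sum(gc$probabilities), 1)

  for (s in 1:25) {
    roi <- random_roi(10, seed = s)
    q <- quantize(roi, 8)
    for (off in list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))) {
      g <- compute_glcm(q, off)
      expect_equal(sum(g$probabilities), 1, tolerance = 1e-9)
      expect_equal(g$probabilities, t(g$probabilities), tolerance = 1e-12)
    }
  }
})

test_that("GLCM features reproduce direct substitutions and conventions", {
  degenerate <- structure(
    list(levels = 2L, probabilities = matrix(c(1, 0, 0, 0), 2, 2)),
    class = "glcm"
  )
  f <- glcm_features(degenerate)
  expect_equal(f[["glcm_energy"]], 1)
  expect_equal(f[["glcm_entropy"]], 0)
  expect_equal(f[["glcm_contrast"]], 0)
  expect_equal(f[["glcm_homogeneity"]], 1)
  expect_equal(f[["glcm_correlation"]], 0)  # zero marginal variance

  checker <- structure(
    list(levels = 2L, probabilities = matrix(c(0, 0.5, 0.5, 0), 2, 2)),
    class = "glcm"
  )
  f2 <- glcm_features(checker)
  expect_equal(f2[["glcm_contrast"]], 1)
  expect_equal(f2[["glcm_energy"]], 0.5)
  expect_equal(f2[["glcm_entropy"]], 1)
  expect_equal(f2[["glcm_homogeneity"]], 0.5)

  for (s in 1:10) {
    g <- compute_glcm(quantize(random_roi(10, s), 8), c(0, 1))
    f <- glcm_features(g)
    expect_gte(f[["glcm_energy"]], 0); expect_lte(f[["glcm_energy"]], 1)
    expect_gte(f[["glcm_entropy"]], 0)
  }
})

test_that("GLDM distribution and features follow the difference law", {
  q2 <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  attr(q2, "levels") <- 2L
  d <- compute_gldm(q2, c(0, 1))
  expect_equal(d$probabilities, c(0, 1))

  dc <- compute_gldm(quantize(const_roi(), 8), c(0, 1))
  expect_equal(dc$probabilities[1], 1)

  f0 <- gldm_features(structure(list(levels = 4L, probabilities = c(1, 0, 0, 0)),
                                class = "gldm"))
  expect_equal(f0[["gldm_mean"]], 0)
  expect_equal(f0[["gldm_contrast"]], 0)
  expect_equal(f0[["gldm_entropy"]], 0)
  expect_equal(f0[["gldm_idm"]], 1)

  f1 <- gldm_features(structure(list(levels = 4L, probabilities = c(0, 1, 0, 0)),
                                class = "gldm"))
  expect_equal(f1[["gldm_mean"]], 1)
  expect_equal(f1[["gldm_contrast"]], 1)
  expect_equal(f1[["gldm_entropy"]], 0)
  expect_equal(f1[["gldm_idm"]], 0.5)

  for (s in 1:10) {
    d <- compute_gldm(quantize(random_roi(10, s), 8), c(-1, 1))
    expect_equal(sum(d$probabilities), 1, tolerance = 1e-9)
    f <- gldm_features(d)
    expect_gte(f[["gldm_variance"]], -1e-12)
  }
})

test_that("spectral features detect a pure sinusoid and degrade gracefully", {
  f0 <- fft_features(const_roi(7, 16))
  expect_true(all(f0 == 0))

  # cosine along x, 8 cycles across a 64-px box: radius 8/64 = 0.125
  n <- 64
  xx <- matrix(rep(0:(n - 1), each = n), n, n, byrow = TRUE)
  wave <- roi_image(100 + 50 * cos(2 * pi * 8 * xx / n))
  f <- fft_features(wave)
  bands <- f[c("fft_band1", "fft_band2", "fft_band3", "fft_band4")]
  expect_equal(sum(bands), 1, tolerance = 1e-9)
  rmax <- sqrt(2) / 2
  k <- ceiling(0.125 / rmax * 4)        # annulus containing radius 0.125
  expect_equal(unname(which.max(bands)), k)
  expect_equal(f[["fft_dominant_freq"]], rmax * (2 * k - 1) / 8)
  expect_equal(f[["fft_mean_freq"]], 0.125, tolerance = 1e-6)

  for (s in 1:10) {
    fr <- fft_features(random_roi(16, s))
    expect_true(all(is.finite(fr)))
    expect_equal(sum(fr[c("fft_band1", "fft_band2", "fft_band3", "fft_band4")]),
                 1, tolerance = 1e-9)
  }
})

test_that("per-modality and per-patient extraction honor the frozen manifest", {
  roi <- random_roi(24, seed = 2)
  v <- extract_modality(roi)
  expect_length(v, 55)
  expect_true(all(is.finite(v)))
  expect_identical(names(v), feature_manifest(per_patient = FALSE))
  expect_identical(v, extract_modality(roi))

  roi2 <- random_roi(24, seed = 3)
  pat <- extract_patient(roi, roi2)
  expect_length(pat, 110)
  expect_identical(names(pat), feature_manifest())
  swapped <- extract_patient(roi2, roi)
  expect_equal(unname(swapped[1:55]), unname(pat[56:110]))
  expect_equal(unname(swapped[56:110]), unname(pat[1:55]))

  golden <- readLines(system.file("extdata", "feature_manifest.txt",
                                  package = "radstrat"))
  expect_identical(feature_manifest(), golden)
})

test_that("intensity shifts move first-order location but not texture features", {
  roi <- random_roi(24, seed = 9)
  shifted <- roi_image(roi$intensities + 37, roi$mask)
  a <- extract_modality(roi)
  b <- extract_modality(shifted)
  expect_equal(b[["hist_mean"]], a[["hist_mean"]] + 37)
  expect_equal(b[["hist_median"]], a[["hist_median"]] + 37)
  texture <- c(grep("^glcm_", names(a), value = TRUE),
               grep("^gldm_", names(a), value = TRUE),
               "hist_entropy", "hist_uniformity", "hist_sd")
  expect_equal(a[texture], b[texture], tolerance = 1e-9)
})

test_that("all 110 features stay finite on degenerate inputs", {
  pat <- extract_patient(const_roi(3, 16), const_roi(900, 16))
  expect_true(all(is.finite(pat)))

  # minimal 16-pixel mask
  mask <- matrix(FALSE, 16, 16); mask[5:8, 5:8] <- TRUE
  tiny <- roi_image(matrix(round(runif(256, 0, 10)), 16, 16), mask)
  expect_true(all(is.finite(extract_patient(tiny, tiny))))
})
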