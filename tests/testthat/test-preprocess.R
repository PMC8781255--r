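test_that("noise level is the (scaled) MAD of the peak intensities", {
  s <- spec_of(c(100, 200, 300, 400, 500), c(1, 2, 3, 4, 100))
  expect_equal(estimate_noise(s), 1)          # median 3, |dev| [2,1,0,1,97]
  expect_equal(estimate_noise(s, mad_scale = 2), 2)
  expect_equal(estimate_noise(spec_of(c(100, 200, 300), c(5, 5, 5))), 0)
  expect_equal(estimate_noise(spec_of(100, 7)), 0)
  expect_error(estimate_noise(msi_spectrum(numeric(0), numeric(0))),
               "empty pixel")
})

test_that("SNR filter keeps peaks at or above snr_min times the noise", {
  s <- spec_of(c(100, 200, 300, 400, 500), c(1, 2, 3, 4, 100))
  f <- snr_filter(s, preprocess_params(snr_min = 3))
  expect_equal(f$intensity, c(3, 4, 100))
  expect_equal(f$mz, c(300, 400, 500))        # m/z order preserved
  # zero noise (constant spectrum) leaves everything untouched
  cs <- spec_of(c(100, 200), c(5, 5))
  expect_equal(snr_filter(cs, preprocess_params(snr_min = 100)), cs)
  # everything below 3x noise: empty spectrum returned
  # (median 60, MAD 40, threshold 120 exceeds every intensity)
  lo <- spec_of(c(100, 200, 300), c(0, 60, 100))
  f2 <- snr_filter(lo, preprocess_params(snr_min = 3))
  expect_equal(length(f2$mz), 0L)
})

test_that("gap-rule alignment merges within tolerance and splits beyond", {
  # 700.0000 vs 700.0140 is 20 ppm: one feature under a 25 ppm tolerance
  sec <- section_of(list(spec_of(700.0000, 10), spec_of(700.0140, 30)))
  fm <- align_section(sec, tol_ppm = 25)
  expect_equal(length(fm$feature_mz), 1L)
  expect_equal(fm$feature_mz, (700.0000 * 10 + 700.0140 * 30) / 40)
  expect_equal(fm$values[, 1], c(10, 30))
  # 50 ppm apart: two features
  sec2 <- section_of(list(spec_of(700.0000, 10), spec_of(700.0350, 30)))
  fm2 <- align_section(sec2, tol_ppm = 25)
  expect_equal(length(fm2$feature_mz), 2L)
  expect_equal(fm2$values, matrix(c(10, NA, NA, 30), 2), ignore_attr = TRUE)
  # single pixel, single peak: identity
  fm3 <- align_section(section_of(list(spec_of(500.5, 7))), 25)
  expect_equal(fm3$feature_mz, 500.5)
  expect_equal(fm3$values[1, 1], 7)
  # plain-mean consensus flag
  fm4 <- align_section(sec, tol_ppm = 25, consensus = "mean")
  expect_equal(fm4$feature_mz, 700.0070)
  expect_error(align_section(section_of(list(
    msi_spectrum(numeric(0), numeric(0)))), 25), "empty")
})

test_that("a pixel contributing several peaks to a cluster keeps the most intense", {
  sec <- section_of(list(spec_of(c(700.0000, 700.0050), c(5, 9)),
                         spec_of(700.0020, 4)))
  fm <- align_section(sec, tol_ppm = 25)
  expect_equal(length(fm$feature_mz), 1L)
  expect_equal(fm$values[, 1], c(9, 4))
  # intensity tie goes to the lower m/z
  sec2 <- section_of(list(spec_of(c(700.0000, 700.0050), c(5, 5))))
  expect_equal(align_section(sec2, 25)$values[1, 1], 5)
})

test_that("alignment equals the brute-force transitive-merge oracle", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(2:200, 1)
    base <- sort(runif(max(1, n %/% 4), 100, 950))
    mz <- sort(sample(base, n, replace = TRUE) *
                 (1 + rnorm(n, 0, 2e-5)))
    mz <- pmin(pmax(mz, 50), 1000)
    mz <- sort(mz + cumsum(rep(1e-9, n)))  # break exact ties
    tol <- sample(c(5, 25, 35), 1)
    got <- gap_clusters(mz, tol)
    want <- oracle_cluster(mz, tol)
    expect_identical(canonical_partition(got), canonical_partition(want))
  }
})

test_that("alignment keeps panel lipids apart but merges jittered copies", {
  spec <- default_phantom_spec()
  panel_mz <- spec$panel$emit_mz
  set.seed(11)
  # 40 pixels, each emitting every panel lipid with 5 ppm jitter
  spectra <- lapply(1:40, function(i) {
    mz <- sort(panel_mz * (1 + rnorm(length(panel_mz), 0, 5e-6)))
    msi_spectrum(mz, rep(100, length(mz)), validate = FALSE)
  })
  fm <- align_section(section_of(spectra), tol_ppm = 25)
  expect_equal(length(fm$feature_mz), length(panel_mz))
  expect_true(all(!is.na(fm$values)))  # >= 99% merged: here all
  # every consensus centroid identifies its lipid uniquely
  idx <- vapply(fm$feature_mz, function(m) which.min(abs(panel_mz - m)),
                integer(1))
  expect_identical(sort(idx), seq_along(panel_mz))
})

test_that("cluster-support prefilter equals align-then-filter", {
  set.seed(99)
  spectra <- lapply(1:30, function(i) {
    mz <- sort(c(700 * (1 + rnorm(1, 0, 5e-6)),
                 runif(sample(0:3, 1), 100, 600)))
    msi_spectrum(mz, runif(length(mz), 1, 10), validate = FALSE)
  })
  sec <- section_of(spectra)
  full <- pixel_frequency_filter(align_section(sec, 25), 0.2)
  pre <- align_section(sec, 25, min_pixels = ceiling(0.2 * 30))
  expect_equal(pre$feature_mz, full$feature_mz)
  expect_equal(pre$values, full$values)
})

test_that("pixel-frequency filter boundary is strictly 'less than'", {
  vals <- matrix(NA_real_, 100, 3)
  vals[1:4, 1] <- 1    # 4% of pixels: removed at 5%
  vals[1:5, 2] <- 1    # exactly 5%: kept
  vals[, 3] <- 1
  fm <- fm_of(vals)
  out <- pixel_frequency_filter(fm, 0.05)
  expect_equal(ncol(out$values), 2L)
  expect_equal(out$feature_mz, fm$feature_mz[2:3])
  expect_equal(nrow(out$values), 100L)           # pixel set unchanged
  expect_equal(pixel_frequency_filter(fm, 0), fm)  # no-op limit
})

test_that("RMS normalization fixes every pixel's root mean square at 1", {
  fm <- fm_of(matrix(c(3, 4, NA, 5), 2, 2, byrow = TRUE))
  out <- rms_normalize(fm)
  expect_equal(out$values[1, ], c(3, 4) / sqrt((9 + 16) / 2))
  expect_equal(out$values[2, ], c(NA, 1))        # single value -> 1
  rms <- sqrt(rowMeans(out$values^2, na.rm = TRUE))
  expect_true(all(abs(rms - 1) < 1e-9))
  bad <- fm_of(matrix(c(1, NA, NA, NA), 2, 2))
  expect_error(rms_normalize(bad), "x=2")
})

test_that("preprocessing runs the fixed stage order and logs it", {
  sim <- simulate_section(default_phantom_spec(), 24, "control", seed = 3)
  pp <- preprocess_section(sim$section)
  expect_identical(pp$log$stage,
                   c("input", "snr_filter", "align", "pixel_filter",
                     "rms_normalize"))
  # feature counts monotone non-increasing through the filters
  nf <- pp$log$n_features[!is.na(pp$log$n_features)]
  expect_true(all(diff(nf) <= 0))
  expect_true(all(diff(pp$log$n_peaks) <= 0))
  rms <- sqrt(rowMeans(pp$fm$values^2, na.rm = TRUE))
  expect_true(all(abs(rms - 1) < 1e-9))
})
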