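two_fm <- function(mz1, mz2, v1 = 10, v2 = 20) {
  list(fm_of(matrix(v1, 1, length(mz1)), feature_mz = mz1, section_id = "s1"),
       fm_of(matrix(v2, 1, length(mz2)), feature_mz = mz2, section_id = "s2"))
}

test_that("study alignment merges section centroids by the gap rule", {
  st <- align_study(two_fm(700.0000, 700.0140), tol_ppm = 35)   # 20 ppm
  expect_equal(length(st$feature_mz), 1L)
  expect_equal(st$values[, 1], c(10, 20))
  st2 <- align_study(two_fm(700.0000, 700.0350), tol_ppm = 35)  # 50 ppm
  expect_equal(length(st2$feature_mz), 2L)
  expect_equal(st2$values, matrix(c(10, NA, NA, 20), 2), ignore_attr = TRUE)
  # single section: identity on centroids and values
  one <- fm_of(matrix(c(1, 2, 3, 4), 2, 2), feature_mz = c(500, 600))
  st3 <- align_study(list(one), 35)
  expect_equal(st3$feature_mz, one$feature_mz)
  expect_equal(st3$values, one$values)
  expect_error(align_study(list()), "no feature matrices")
})

test_that("study alignment is permutation-invariant in section order", {
  set.seed(5)
  fms <- lapply(1:4, function(i) {
    mz <- sort(c(400, 500, 600) * (1 + rnorm(3, 0, 5e-6)))
    fm_of(matrix(runif(6, 1, 9), 2, 3), feature_mz = mz,
          section_id = paste0("s", i))
  })
  a <- align_study(fms, 35)
  b <- align_study(rev(fms), 35)
  expect_equal(a$feature_mz, b$feature_mz, tolerance = 1e-12)
  key_a <- a$pixel_meta$section_id
  key_b <- b$pixel_meta$section_id
  expect_equal(a$values[order(key_a), ], b$values[order(key_b), ],
               ignore_attr = TRUE)
})

test_that("blank removal applies the 10x median rule with exact boundaries", {
  # study: 2 features; pixel medians 9 and 11; blank median 1 for both
  study <- fm_of(matrix(c(9, 9, 11, 11), 2, 2),
                 feature_mz = c(500.000, 600.000))
  blank <- fm_of(matrix(1, 2, 2), feature_mz = c(500.001, 600.001),
                 section_id = "blank")
  out <- remove_background(study, blank, fold = 10, tol_ppm = 35)
  expect_equal(out$feature_mz, 600.000)          # 9 < 10*1 removed; 11 kept
  rem <- attr(out, "background_removed")
  expect_equal(rem$feature_mz, 500.000)
  expect_equal(rem$tissue_median, 9)
  # feature absent from the blank is kept regardless of intensity
  study2 <- fm_of(matrix(0.5, 2, 1), feature_mz = 700)
  out2 <- remove_background(study2, blank, fold = 10)
  expect_equal(out2$feature_mz, 700)
  expect_error(remove_background(study, subset_fm(blank, pixels = integer(0))),
               "no pixels")
})

test_that("missing values bias the tissue median toward removal by default", {
  # feature observed brightly in 1 of 5 pixels: median over all pixels
  # (missing -> 0) is 0, so it is removed even though observed values are big
  study <- fm_of(matrix(c(100, NA, NA, NA, NA), 5, 1), feature_mz = 500.000)
  blank <- fm_of(matrix(1, 2, 1), feature_mz = 500.001, section_id = "b")
  expect_equal(ncol(remove_background(study, blank)$values), 0L)
  # observed-only medians keep it
  out <- remove_background(study, blank, missing_as_zero = FALSE)
  expect_equal(out$feature_mz, 500.000)
})

test_that("calibrant drift monitoring matches the printed arithmetic", {
  # printed-precision calibrant constant for the worked arithmetic
  d0 <- monitor_drift(443.2335, theoretical_mz = 443.2335)
  expect_equal(d0$ppm_error, 0)
  expect_false(d0$recalibrate)
  d1 <- monitor_drift(443.2446, theoretical_mz = 443.2335)
  expect_equal(d1$ppm_error, 25.04, tolerance = 1e-3)
  expect_true(d1$recalibrate)
  d2 <- monitor_drift(443.2390, theoretical_mz = 443.2335)
  expect_equal(d2$ppm_error, 12.4, tolerance = 1e-2)
  expect_false(d2$recalibrate)
  # the full-precision default agrees to printed precision
  expect_equal(monitor_drift(443.2446)$ppm_error, 25.04, tolerance = 4e-3)
  expect_error(monitor_drift(-1), "positive")
})

test_that("rhodamine 6G conventions reproduce both printed values", {
  expect_equal(round(rhodamine_6g_mz(), 4), 443.2335)
  expect_equal(round(rhodamine_6g_mz(electron_correction = TRUE), 4),
               443.2329)
})

test_that("polyalanine series follows residue + water + proton arithmetic", {
  s <- polyalanine_series(2, 13)
  expect_equal(unname(s[["5"]]), 374.2034, tolerance = 5e-5)
  expect_equal(unname(s[["2"]]), 161.0921, tolerance = 5e-5)
  expect_equal(unique(round(diff(s), 5)), 71.03711)   # constant spacing
  expect_true(all(s >= 50 & s <= 1000))
  expect_gt(max(polyalanine_series(2, 20)), 900)      # spans the range
  expect_lte(max(polyalanine_series(2, 20)), 1000)    # but is clipped
  expect_error(polyalanine_series(1, 5), "invalid")
  expect_error(polyalanine_series(5, 3), "invalid")
})

test_that("recalibration recovers injected drift", {
  theo <- polyalanine_series(3, 12)
  # zero drift: identity model
  m0 <- fit_recalibration(theo, theo, "constant_ppm")
  expect_equal(m0$coefficients[["intercept"]], 0)
  expect_equal(apply_recalibration(m0, c(100, 500, 900)), c(100, 500, 900))
  # uniform +20 ppm shift: constant model recovers to < 0.1 ppm
  obs <- theo * (1 + 20e-6)
  m1 <- fit_recalibration(obs, theo, "constant_ppm")
  expect_lt(m1$fit_residual_ppm, 1e-9)
  corr <- apply_recalibration(m1, obs)
  expect_lt(max(abs((corr - theo) / theo * 1e6)), 0.1)
  # linear drift 5 -> 30 ppm over 100-1000 Da
  theo2 <- seq(100, 1000, by = 100)
  drift <- 5 + (30 - 5) * (theo2 - 100) / 900
  obs2 <- theo2 * (1 + drift * 1e-6)
  m2 <- fit_recalibration(obs2, theo2, "linear_in_mz")
  expect_lt(m2$fit_residual_ppm, 1)
  corr2 <- apply_recalibration(m2, obs2)
  expect_lt(max(abs((corr2 - theo2) / theo2 * 1e6)), 0.1)
  expect_error(fit_recalibration(c(500, 500), c(500, 500), "linear_in_mz"),
               "distinct")
})

test_that("recalibration is inverse-consistent on distorted feature matrices", {
  fm <- fm_of(matrix(1, 1, 3), feature_mz = c(200, 500, 800))
  model <- fit_recalibration(c(200, 500, 800) * (1 + 15e-6),
                             c(200, 500, 800), "constant_ppm")
  distorted <- fm
  distorted$feature_mz <- fm$feature_mz * (1 + 15e-6)
  back <- apply_recalibration(model, distorted)
  expect_lt(max(abs((back$feature_mz - fm$feature_mz) /
                      fm$feature_mz * 1e6)), 0.1)
  # spectra are corrected too
  sp <- apply_recalibration(model, spec_of(500 * (1 + 15e-6)))
  expect_lt(abs(sp$mz - 500) / 500 * 1e6, 0.1)
})
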