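test_that("balanced sampling draws n per group, reproducibly", {
  sizes <- c(a = 500, b = 500, c = 300, d = 250)
  fm <- fm_of(matrix(1, sum(sizes), 2),
              region = rep(names(sizes), sizes))
  out <- balanced_sample(fm, n_per_group = 200, seed = 9)
  expect_equal(nrow(out$values), 800L)
  expect_true(all(table(out$pixel_meta$region_label) == 200))
  # small group taken whole with a warning
  fm2 <- fm_of(matrix(1, 350, 1), region = rep(c("a", "b"), c(150, 200)))
  expect_warning(out2 <- balanced_sample(fm2, n_per_group = 200, seed = 1),
                 "only 150")
  expect_equal(sum(out2$pixel_meta$region_label == "a"), 150L)
  # same seed, same pixels
  s1 <- balanced_sample(fm, n_per_group = 50, seed = 4)
  s2 <- balanced_sample(fm, n_per_group = 50, seed = 4)
  expect_identical(s1$pixel_meta, s2$pixel_meta)
})

test_that("group presence filter is per-group, then pixels are filtered", {
  # feature 1: 60% of egg pixels, 10% elsewhere -> kept (per-group rule)
  # feature 2: at most 40% of every group -> removed
  # feature 3: fully observed -> kept
  set.seed(2)
  region <- rep(c("eggs", "gut"), each = 50)
  v <- matrix(NA_real_, 100, 3)
  v[c(sample(1:50, 30), sample(51:100, 5)), 1] <- 1
  v[sample(1:100, 40), 2] <- 1
  v[, 3] <- 1
  fm <- fm_of(v, region = region)
  out <- group_filters(fm, group_presence_frac = 0.5,
                       pixel_missing_frac = 0.9)
  expect_equal(out$feature_mz, fm$feature_mz[c(1, 3)])
  # fully observed matrix passes unchanged
  full <- fm_of(matrix(1, 10, 2), region = rep("a", 10))
  expect_equal(group_filters(full)$values, full$values)
  # pixel missingness rule drops sparse pixels after the feature rule
  v2 <- matrix(1, 10, 4)
  v2[1, 1:3] <- NA                       # pixel 1 misses 75% of features
  fm2 <- fm_of(v2, region = rep("a", 10))
  out2 <- group_filters(fm2, pixel_missing_frac = 0.5)
  expect_equal(nrow(out2$values), 9L)
  expect_error(group_filters(fm_of(matrix(NA_real_, 4, 1),
                                   region = rep("a", 4))),
               "every feature")
})

test_that("KNN imputation fills every gap from the nearest pixels", {
  x <- matrix(1:12, 4, 3)
  expect_identical(knn_impute(x, 5), x)        # complete: identity
  # three identical pixels, one missing entry: forced by the mean
  y <- matrix(rep(c(2, 7, 4), each = 3), 3, 3)
  y[2, 3] <- NA
  out <- knn_impute(y, k = 2)
  expect_equal(out[2, 3], 4)
  # neighbour count capped by eligibility: k = 5 but only 2 pixels
  # observe the feature, so both are averaged
  z <- rbind(c(1, 1, NA), c(1.1, 1.1, 4), c(50, 50, 6))
  out2 <- knn_impute(z, k = 5)
  expect_equal(out2[1, 3], 5)
  expect_false(anyNA(out2))
  # k = 1 takes only the nearest (pixel 2)
  expect_equal(knn_impute(z, k = 1)[1, 3], 4)
  expect_error(knn_impute(matrix(c(NA, NA, 1, 2), 2, 2), 1),
               "zero pixels")
})

test_that("KNN imputation beats column means on structured data", {
  set.seed(31)
  # low-rank structure: two pixel archetypes
  base <- rbind(matrix(rep(c(10, 20, 5, 8, 15), each = 30), 30),
                matrix(rep(c(2, 3, 12, 25, 4), each = 30), 30))
  x <- base * matrix(rlnorm(length(base), 0, 0.1), nrow(base))
  miss <- matrix(runif(length(x)) < 0.1, nrow(x))
  miss[rowSums(miss) == ncol(x), 1] <- FALSE
  xm <- x; xm[miss] <- NA
  knn <- knn_impute(xm, k = 5)
  colmean <- xm
  for (j in seq_len(ncol(xm)))
    colmean[is.na(xm[, j]), j] <- mean(xm[, j], na.rm = TRUE)
  rmse <- function(imp) sqrt(mean((imp[miss] - x[miss])^2))
  expect_lt(rmse(knn), rmse(colmean))
})

test_that("pareto scaling centers and divides by root-sd", {
  out <- pareto_scale(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_equal(out[, "a"], c(-1, 0, 1))        # mean 2, sd 1
  expect_equal(out[, "b"], c(0, 0, 0))         # constant column
  set.seed(8)
  x <- matrix(rlnorm(60), 20, 3)
  expect_equal(colMeans(pareto_scale(x)), rep(0, 3), tolerance = 1e-12)
  expect_error(pareto_scale(matrix(c(1, NA), 2, 1)), "complete")
})

test_that("PCA by SVD has the documented variance, sign and identity", {
  # points on a line: PC1 explains everything
  t <- seq(-1, 1, length.out = 20)
  line <- cbind(t, 2 * t, -t)
  p <- pca_features(line, 2)
  expect_equal(p$var_explained[1], 1)
  # orthonormal loadings, sign convention, reconstruction
  set.seed(12)
  x <- scale(matrix(rnorm(200), 40, 5), scale = FALSE)
  p2 <- pca_features(x, 5)
  expect_equal(t(p2$loadings) %*% p2$loadings, diag(5), tolerance = 1e-10)
  for (j in 1:5) {
    v <- p2$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_equal(p2$scores %*% t(p2$loadings), x, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_true(all(diff(p2$var_explained) <= 1e-12))
  expect_equal(sum(p2$var_explained), 1)
  # isotropic 2-d cloud: halves, approximately
  set.seed(3)
  iso <- scale(matrix(rnorm(8000), 4000, 2), scale = FALSE)
  expect_equal(pca_features(iso, 2)$var_explained, c(0.5, 0.5),
               tolerance = 0.05)
  expect_error(pca_features(line, 7), "exceeds")
})

test_that("confidence-ellipse filter removes the right pixels", {
  set.seed(44)
  x <- matrix(rnorm(600), 300, 2) %*% chol(matrix(c(2, 1, 1, 1.5), 2))
  x <- sweep(x, 2, c(50, 60), "+")     # keep values positive
  fm <- fm_of(x, region = rep("g", 300))
  # conf -> 1: the chi-square quantile diverges and nothing is removed
  out2 <- ellipse_outlier_filter(fm, conf = 1 - 1e-15)
  expect_equal(nrow(out2$values), 300L)
  # one extreme pixel 10 sd away is always removed at 0.95
  fm$values[7, ] <- c(50, 60) + c(40, -40)
  out <- ellipse_outlier_filter(fm, conf = 0.95)
  expect_false(any(out$pixel_meta$x == 7))
  # groups below 3 pixels are skipped, not errored
  tiny <- fm_of(matrix(c(1, 2, 4, 8), 2, 2), region = c("a", "a"))
  expect_equal(nrow(ellipse_outlier_filter(tiny)$values), 2L)
})

test_that("per-section medians aggregate to one row per replicate", {
  v <- rbind(c(1, 10), c(2, 20), c(9, 30),     # section A eggs
             c(5, NA), c(6, NA), c(7, NA))     # section B eggs
  fm <- fm_of(v, section_id = rep(c("A", "B"), each = 3),
              region = "eggs", treatment = rep(c("control", "BPA"), each = 3),
              time_h = 48)
  med <- median_by_section(fm, region = "eggs")
  expect_equal(dim(med), c(2L, 2L))
  expect_equal(unname(med["A", 1]), 2)         # median of 1, 2, 9
  expect_true(is.na(med["B", 2]))              # all-missing stays missing
  meta <- attr(med, "meta")
  expect_equal(meta$treatment, c("control", "BPA"))
  # six sections -> six rows
  fm6 <- fm_of(matrix(1, 18, 1), section_id = rep(paste0("s", 1:6), each = 3),
               region = "eggs")
  expect_equal(nrow(median_by_section(fm6, "eggs")), 6L)
  expect_error(median_by_section(fm, region = "eye"), "no pixels")
})

test_that("rank tests match exact enumeration and handle degeneracy", {
  # a = 1,2,3 vs b = 4,5,6: the most extreme of the 20 assignments
  rt <- rank_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rt$p_value, 0.1)
  expect_equal(rt$statistic, 0)
  # full-enumeration agreement for n <= 6 per group, no ties
  set.seed(17)
  for (i in 1:40) {
    a <- round(rnorm(sample(2:6, 1), 0, 5), 3)
    b <- round(rnorm(sample(2:6, 1), 1, 5), 3)
    expect_equal(rank_test(a, b)$p_value, oracle_ranksum_p(a, b),
                 tolerance = 1e-10)
  }
  # degenerate inputs
  expect_warning(p1 <- rank_test(c(2, 2), c(2, 2))$p_value, "tied")
  expect_equal(p1, 1)
  expect_warning(p2 <- rank_test(c(1, 2, 3), c(1, 2, 3),
                                 mode = "paired_signed_rank")$p_value,
                 "zero")
  expect_equal(p2, 1)
  expect_error(rank_test(1:3, 1:4, mode = "paired_signed_rank"),
               "equal lengths")
  expect_error(rank_test(numeric(0), 1), "non-empty")
  # paired mode recovers a clear shift
  set.seed(23)
  a <- rnorm(12); b <- a + 1
  expect_lt(rank_test(b, a, mode = "paired_signed_rank")$p_value, 0.01)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.4), 0.4)               # m = 1 unchanged
  expect_equal(bh_fdr(rep(0.5, 7)), rep(0.5, 7))
  set.seed(29)
  for (i in 1:25) {
    p <- runif(sample(1:10, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # order-preserving
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("feature contrasts report direction and FDR", {
  set.seed(51)
  n <- 40
  up <- c(rlnorm(n, log(10), 0.2), rlnorm(n, log(20), 0.2))
  down <- c(rlnorm(n, log(10), 0.2), rlnorm(n, log(5), 0.2))
  flat <- rlnorm(2 * n, log(10), 0.2)
  fm <- fm_of(cbind(up, down, flat),
              treatment = rep(c("control", "BPA"), each = n))
  res <- test_features(fm)
  expect_equal(res$direction[1:2], c(1, -1))
  expect_true(all(res$fdr_adjusted_p[1:2] < 0.01))
  expect_gt(res$p_value[3], 0.01)
  expect_true(all(res$fdr_adjusted_p >= res$p_value - 1e-12))
})
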