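# Statistical core: balanced pixel sampling, per-group presence filters,
# confidence-ellipse outlier removal, KNN imputation, pareto scaling, PCA,
# per-section median aggregation, rank tests and BH-FDR.

#' Statistical parameters
#'
#' @param n_per_group Pixels sampled per group (default 200).
#' @param group_presence_frac A feature must be observed in at least this
#'   fraction of pixels of at least one group (default 0.5).
#' @param pixel_missing_frac Pixels missing more than this fraction of the
#'   retained features are dropped (default 0.5).
#' @param ellipse_conf Confidence level of the PCA score ellipse used for
#'   outlier removal (default 0.95).
#' @param knn_k Neighbour count for imputation (default 5).
#' @param seed RNG seed for the sampling steps.
#' @return A list of class `stats_params`.
#' @export
stats_params <- function(n_per_group = 200, group_presence_frac = 0.5,
                         pixel_missing_frac = 0.5, ellipse_conf = 0.95,
                         knn_k = 5, seed = 1L) {
  stopifnot(n_per_group >= 1,
            group_presence_frac > 0, group_presence_frac < 1,
            pixel_missing_frac > 0, pixel_missing_frac < 1,
            ellipse_conf > 0, ellipse_conf < 1, knn_k >= 1)
  structure(list(n_per_group = n_per_group,
                 group_presence_frac = group_presence_frac,
                 pixel_missing_frac = pixel_missing_frac,
                 ellipse_conf = ellipse_conf, knn_k = knn_k,
                 seed = as.integer(seed)), class = "stats_params")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Sample a balanced set of pixels per group
#'
#' Uniform sampling without replacement of `n_per_group` pixels from each
#' group, so that no single tissue dominates the multivariate analysis.
#' Groups smaller than `n_per_group` are taken whole with a warning.
#'
#' @param fm A [feature_matrix].
#' @param group_col Column of `pixel_meta` defining the groups (default
#'   `"region_label"`).
#' @param n_per_group Pixels per group (default 200).
#' @param seed RNG seed; the same seed reproduces the same pixel set.
#' @return The sampled [feature_matrix].
#' @export
balanced_sample <- function(fm, group_col = "region_label",
                            n_per_group = 200, seed = 1L) {
  g <- fm$pixel_meta[[group_col]]
  if (is.null(g)) stop("grouping column '", group_col, "' not found",
                       call. = FALSE)
  keep_rows <- which(!is.na(g))
  if (length(keep_rows) == 0L) stop("no pixels carry a group label", call. = FALSE)
  idx <- with_seed(seed, {
    unlist(lapply(split(keep_rows, g[keep_rows]), function(rows) {
      if (length(rows) < n_per_group) {
        warning(sprintf("group '%s' has only %d pixels (< %d); taking all",
                        g[rows[1]], length(rows), n_per_group), call. = FALSE)
        rows
      } else sample(rows, n_per_group)
    }), use.names = FALSE)
  })
  subset_fm(fm, pixels = sort(idx))
}

#' Apply the per-group presence and per-pixel missingness filters
#'
#' First keeps features observed in at least `group_presence_frac` of the
#' pixels of *at least one* group (a per-group rule, so tissue-specific
#' lipids survive), then drops pixels missing more than
#' `pixel_missing_frac` of the retained features. The order is fixed:
#' features first.
#'
#' @param fm A [feature_matrix] with group labels.
#' @param group_col Grouping column in `pixel_meta`.
#' @param group_presence_frac Feature presence threshold (default 0.5).
#' @param pixel_missing_frac Pixel missingness threshold (default 0.5).
#' @return The filtered [feature_matrix].
#' @export
group_filters <- function(fm, group_col = "region_label",
                          group_presence_frac = 0.5,
                          pixel_missing_frac = 0.5) {
  g <- fm$pixel_meta[[group_col]]
  groups <- unique(g[!is.na(g)])
  if (length(groups) == 0L) stop("no group labels present", call. = FALSE)
  pres <- sapply(groups, function(gr) {
    rows <- which(g == gr)
    colMeans(!is.na(fm$values[rows, , drop = FALSE]))
  })
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = ncol(fm$values))
  keep_feat <- apply(pres, 1, max) >= group_presence_frac
  if (!any(keep_feat))
    stop("presence filter removed every feature", call. = FALSE)
  fm <- subset_fm(fm, features = which(keep_feat))
  miss <- rowMeans(is.na(fm$values))
  subset_fm(fm, pixels = which(miss <= pixel_missing_frac))
}

#' Impute missing values by k-nearest neighbours
#'
#' Distances between pixels are Euclidean over mutually observed features,
#' scaled by the square root of the overlap size (i.e. root mean squared
#' difference) so distances are comparable across different overlaps. Each
#' missing entry becomes the mean of the k nearest pixels that observe
#' that feature; pixels lacking k eligible neighbours use all eligible
#' ones. Deterministic: distance ties are broken by pixel order.
#'
#' @param x A [feature_matrix] or a numeric matrix with `NA` for missing.
#' @param k Neighbour count (default 5).
#' @return Completed object of the same class; no missing entries remain.
#' @export
knn_impute <- function(x, k = 5) {
  fm <- NULL
  if (inherits(x, "feature_matrix")) { fm <- x; x <- x$values }
  if (!anyNA(x)) return(if (is.null(fm)) x else fm)
  obs <- !is.na(x)
  if (any(colSums(obs) == 0L))
    stop("feature observed in zero pixels cannot be imputed", call. = FALSE)
  if (any(rowSums(obs) == 0L))
    stop("pixel with no observed features cannot be imputed", call. = FALSE)
  x0 <- x; x0[!obs] <- 0
  m <- obs * 1
  sq <- x0^2
  overlap <- m %*% t(m)
  cross <- x0 %*% t(x0)
  si <- sq %*% t(m)
  ss <- si + t(si) - 2 * cross
  ss[ss < 0] <- 0          # numerical noise
  d <- sqrt(ss / pmax(overlap, 1))
  d[overlap == 0] <- Inf   # no mutually observed features
  diag(d) <- Inf

  out <- x
  for (i in which(rowSums(!obs) > 0)) {
    for (j in which(!obs[i, ])) {
      elig <- which(obs[, j] & is.finite(d[i, ]))
      if (length(elig) == 0L) {
        out[i, j] <- mean(x[obs[, j], j])
        next
      }
      nb <- elig[order(d[i, elig], elig)][seq_len(min(k, length(elig)))]
      out[i, j] <- mean(x[nb, j])
    }
  }
  if (is.null(fm)) out else { fm$values <- out; fm }
}

#' Pareto-scale a complete matrix
#'
#' Per feature: `(x - mean) / sqrt(sd)` with the sample standard
#' deviation, the usual metabolomics compromise between unit variance and
#' no scaling. Constant features become columns of zeros.
#'
#' @param x Complete numeric matrix (pixels x features).
#' @return The scaled matrix; every column has mean 0.
#' @export
pareto_scale <- function(x) {
  if (anyNA(x)) stop("pareto scaling requires a complete matrix", call. = FALSE)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  out <- sweep(x, 2, mu)
  nz <- sd > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sqrt(sd[nz]), "/")
  out[, !nz] <- 0
  out
}

#' Principal component analysis by SVD
#'
#' Applied to an already centered/scaled complete matrix. The explained
#' variance of component i is `sigma_i^2 / sum(sigma^2)`. Sign convention
#' for reproducibility: the largest-magnitude element of each loading
#' vector is positive.
#'
#' @param x Complete numeric matrix (pixels x features), centered/scaled.
#' @param n_components Number of components (default
#'   `min(dim(x))`).
#' @return An object of class `msi_pca`: `scores` (pixels x components),
#'   `loadings` (features x components, orthonormal columns),
#'   `var_explained`.
#' @export
pca_features <- function(x, n_components = min(dim(x))) {
  if (n_components > min(dim(x)))
    stop("n_components exceeds matrix rank bound", call. = FALSE)
  sv <- svd(x, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(sv$v, 2, flip, "*")
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(n_components)], n_components),
                  2, flip, "*")
  structure(list(scores = scores, loadings = loadings,
                 var_explained = sv$d^2 / sum(sv$d^2),
                 sdev = sv$d / sqrt(max(1, nrow(x) - 1))),
            class = "msi_pca")
}

#' @export
print.msi_pca <- function(x, ...) {
  cat(sprintf("<msi_pca> %d x %d scores; var explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%",
                            100 * x$var_explained[seq_len(min(3, length(x$var_explained)))]),
                    collapse = ", ")))
  invisible(x)
}

#' Remove pixels outside a PCA confidence ellipse
#'
#' Per group: the group's pixels are KNN-imputed, pareto-scaled and
#' projected onto PC1--PC2; pixels whose squared Mahalanobis distance
#' under the group's 2x2 score covariance exceeds the chi-square quantile
#' with 2 degrees of freedom at `conf` (5.991 at 0.95) are removed. Groups
#' with singular score covariance are skipped with a warning.
#'
#' @param fm A [feature_matrix] with group labels.
#' @param group_col Grouping column in `pixel_meta`.
#' @param conf Ellipse confidence level (default 0.95).
#' @param k Imputation neighbour count (default 5).
#' @return The filtered [feature_matrix].
#' @export
ellipse_outlier_filter <- function(fm, group_col = "region_label",
                                   conf = 0.95, k = 5) {
  g <- fm$pixel_meta[[group_col]]
  groups <- unique(g[!is.na(g)])
  cutoff <- stats::qchisq(conf, df = 2)
  drop <- logical(nrow(fm$values))
  for (gr in groups) {
    rows <- which(g == gr)
    if (length(rows) < 3L) next
    x <- fm$values[rows, , drop = FALSE]
    # features unobserved within this group carry no information about
    # the group's pixel scatter and cannot be imputed from it
    x <- x[, colSums(!is.na(x)) > 0, drop = FALSE]
    x <- knn_impute(x, k = k)
    x <- pareto_scale(x)
    sc <- pca_features(x, n_components = 2)$scores
    cv <- stats::cov(sc)
    if (abs(det(cv)) < 1e-12) {
      warning(sprintf("group '%s' has singular score covariance; skipped", gr),
              call. = FALSE)
      next
    }
    d2 <- stats::mahalanobis(sc, colMeans(sc), cv)
    drop[rows[d2 > cutoff]] <- TRUE
  }
  subset_fm(fm, pixels = which(!drop))
}

#' Per-section, per-feature median intensities
#'
#' Aggregates pixel intensities to one row per tissue section (i.e. per
#' biological replicate): the median over the observed values of the
#' region's pixels. Sections with no pixels in the region are excluded
#' with a warning.
#'
#' @param fm A [feature_matrix].
#' @param region Restrict to pixels with this `region_label` (default
#'   `NULL`: all pixels).
#' @return A numeric matrix sections x features with a `meta` attribute
#'   (section_id, time_point_h, treatment per row); entries are `NA` when
#'   a feature is unobserved in a section's region.
#' @export
median_by_section <- function(fm, region = NULL) {
  rows <- seq_len(nrow(fm$values))
  if (!is.null(region))
    rows <- rows[!is.na(fm$pixel_meta$region_label) &
                   fm$pixel_meta$region_label == region]
  if (length(rows) == 0L)
    stop("no pixels in region '", region, "'", call. = FALSE)
  secs <- unique(fm$pixel_meta$section_id)
  present <- vapply(secs, function(s)
    any(fm$pixel_meta$section_id[rows] == s), logical(1))
  if (!all(present))
    warning("sections with zero region pixels excluded: ",
            paste(secs[!present], collapse = ", "), call. = FALSE)
  secs <- secs[present]
  out <- do.call(rbind, lapply(secs, function(s) {
    r <- rows[fm$pixel_meta$section_id[rows] == s]
    apply(fm$values[r, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  }))
  out[is.nan(out)] <- NA
  rownames(out) <- secs
  colnames(out) <- sprintf("%.4f", fm$feature_mz)
  meta <- do.call(rbind, lapply(secs, function(s) {
    i <- which(fm$pixel_meta$section_id == s)[1]
    data.frame(section_id = s,
               time_point_h = fm$pixel_meta$time_point_h[i],
               treatment = fm$pixel_meta$treatment[i])
  }))
  attr(out, "meta") <- meta
  out
}

#' Two-sample rank test
#'
#' `pixel_rank_sum` is the Mann--Whitney rank-sum test, with the exact
#' distribution when the smaller sample has at most 8 values and no ties
#' are present, otherwise the tie-corrected normal approximation.
#' `paired_signed_rank` is the Wilcoxon signed-rank test on paired
#' differences. Degenerate inputs (all values tied across both samples,
#' or all paired differences zero) yield p = 1 with a warning.
#'
#' @param a,b Numeric samples (equal length for the paired mode).
#' @param mode `"pixel_rank_sum"` (default) or `"paired_signed_rank"`.
#' @return List with `statistic` and two-sided `p_value`.
#' @export
rank_test <- function(a, b, mode = c("pixel_rank_sum", "paired_signed_rank")) {
  mode <- match.arg(mode)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (mode == "paired_signed_rank") {
    if (length(a) != length(b))
      stop("paired mode requires equal lengths", call. = FALSE)
    d <- a - b
    if (all(d == 0)) {
      warning("all paired differences are zero; p = 1", call. = FALSE)
      return(list(statistic = NA_real_, p_value = 1))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = sum(d != 0) <= 8))
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value))
  }
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied across both groups; p = 1", call. = FALSE)
    return(list(statistic = NA_real_, p_value = 1))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Benjamini--Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_i = min_{j >= rank(i)} (m / j) p_(j)`,
#' capped at 1 and order-preserving (delegates to [stats::p.adjust()]).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Per-feature group contrast with FDR control
#'
#' Runs [rank_test()] for every feature between two groups of pixels (or
#' paired per-section medians) and applies BH-FDR. The direction is the
#' sign of the (exposed - reference) median difference.
#'
#' @param fm A [feature_matrix].
#' @param group_col Column of `pixel_meta` splitting the two groups
#'   (default `"treatment"`).
#' @param ref,alt Reference and contrast group values (defaults
#'   `"control"`, `"BPA"`).
#' @param mode Passed to [rank_test()].
#' @return Data frame: `feature_mz`, `statistic`, `p_value`,
#'   `fdr_adjusted_p`, `direction`.
#' @export
test_features <- function(fm, group_col = "treatment", ref = "control",
                          alt = "BPA", mode = "pixel_rank_sum") {
  g <- fm$pixel_meta[[group_col]]
  ra <- which(g == alt); rr <- which(g == ref)
  if (length(ra) == 0L || length(rr) == 0L)
    stop("both contrast groups must contain pixels", call. = FALSE)
  res <- lapply(seq_along(fm$feature_mz), function(j) {
    va <- fm$values[ra, j]; vr <- fm$values[rr, j]
    va <- va[!is.na(va)]; vr <- vr[!is.na(vr)]
    if (length(va) == 0L || length(vr) == 0L)
      return(data.frame(feature_mz = fm$feature_mz[j], statistic = NA_real_,
                        p_value = NA_real_, direction = NA_real_))
    rt <- rank_test(va, vr, mode = mode)
    data.frame(feature_mz = fm$feature_mz[j], statistic = rt$statistic,
               p_value = rt$p_value,
               direction = sign(stats::median(va) - stats::median(vr)))
  })
  out <- do.call(rbind, res)
  out$fdr_adjusted_p <- bh_fdr(out$p_value)
  out[, c("feature_mz", "statistic", "p_value", "fdr_adjusted_p", "direction")]
}
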