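# Study-level assembly: merge per-section feature matrices, remove
# blank-slide background ions, and the calibration QC arithmetic (drift
# monitoring against rhodamine 6G, polyalanine recalibration).

#' Align per-section feature matrices into a study matrix
#'
#' Clusters the section-level consensus centroids with the same
#' single-linkage ppm gap rule used within sections, weighting each
#' centroid by its total feature intensity. Pixel values are carried over
#' unchanged; a feature unmatched in a section is missing for that
#' section's pixels. When two features of the same section fall into one
#' study cluster their per-pixel values are summed.
#'
#' @param fms List of [feature_matrix] objects, one per section, each
#'   internally aligned.
#' @param tol_ppm Study-level tolerance in ppm (default 35, looser than
#'   the within-section 25 ppm to absorb multi-day drift).
#' @return A [feature_matrix] spanning all pixels of all sections, with a
#'   `provenance` attribute mapping study features to the contributing
#'   section features.
#' @export
align_study <- function(fms, tol_ppm = 35) {
  if (length(fms) == 0L) stop("no feature matrices to align", call. = FALSE)
  cent <- unlist(lapply(fms, `[[`, "feature_mz"), use.names = FALSE)
  wt <- unlist(lapply(fms, function(f) colSums(f$values, na.rm = TRUE)),
               use.names = FALSE)
  nfeat <- vapply(fms, function(f) length(f$feature_mz), integer(1))
  src_sec <- rep.int(seq_along(fms), nfeat)
  src_col <- unlist(lapply(nfeat, seq_len), use.names = FALSE)

  o <- order(cent)
  cent <- cent[o]; wt <- wt[o]; src_sec <- src_sec[o]; src_col <- src_col[o]
  cl <- gap_clusters(cent, tol_ppm)
  ncl <- cl[length(cl)]
  w <- ifelse(rep(as.vector(rowsum(wt, cl))[cl] > 0, 1), wt, 1)
  centers <- as.vector(rowsum(cent * w, cl) / rowsum(w, cl))

  npix <- vapply(fms, function(f) nrow(f$values), integer(1))
  row_off <- cumsum(c(0L, npix[-length(npix)]))
  vals <- matrix(NA_real_, nrow = sum(npix), ncol = ncl)
  for (k in seq_along(cl)) {
    s <- src_sec[k]; j <- cl[k]
    rows <- row_off[s] + seq_len(npix[s])
    v <- fms[[s]]$values[, src_col[k]]
    old <- vals[rows, j]
    merge <- !is.na(old) & !is.na(v)
    vals[rows, j] <- ifelse(merge, old + v, ifelse(is.na(v), old, v))
  }
  meta <- do.call(rbind, lapply(fms, `[[`, "pixel_meta"))
  rownames(meta) <- NULL
  shapes <- do.call(c, lapply(fms, `[[`, "grid_shapes"))
  shapes <- shapes[!duplicated(names(shapes))]

  sec_ids <- vapply(fms, function(f) f$pixel_meta$section_id[1], character(1))
  fm <- feature_matrix(centers, vals, meta, grid_shapes = shapes,
                       validate = FALSE)
  attr(fm, "provenance") <- data.frame(
    study_feature = cl, section_id = sec_ids[src_sec], section_mz = cent)
  fm
}

#' Remove blank-slide background ions from a study matrix
#'
#' Study features are matched to blank features with the same ppm gap rule
#' (shared cluster within `tol_ppm`). For each matched feature the median
#' tissue intensity `M_t` (over all study pixels) is compared with the
#' median blank intensity `M_b`; the feature is removed iff
#' `M_t < fold * M_b`. Unmatched features are always kept. Medians treat
#' missing values as 0 by default, so a feature absent from most tissue
#' pixels is correctly biased toward removal; `missing_as_zero = FALSE`
#' restricts the medians to observed values.
#'
#' @param study Study-level [feature_matrix] from [align_study()].
#' @param blank [feature_matrix] of the pooled blank slides, preprocessed
#'   with the same parameters as the tissue sections.
#' @param fold Removal threshold on the tissue/blank median ratio
#'   (default 10).
#' @param tol_ppm Matching tolerance (default 35).
#' @param missing_as_zero Treat missing values as 0 in the medians
#'   (default `TRUE`).
#' @return The filtered [feature_matrix], with a `background_removed`
#'   attribute listing the removed features and their medians.
#' @export
remove_background <- function(study, blank, fold = 10, tol_ppm = 35,
                              missing_as_zero = TRUE) {
  if (nrow(blank$values) == 0L)
    stop("blank feature matrix has no pixels", call. = FALSE)
  med <- function(x) {
    if (missing_as_zero) x[is.na(x)] <- 0 else x <- x[!is.na(x)]
    if (length(x) == 0L) return(0)
    stats::median(x)
  }
  pool <- c(study$feature_mz, blank$feature_mz)
  src <- rep(c("study", "blank"), c(length(study$feature_mz),
                                    length(blank$feature_mz)))
  idx <- c(seq_along(study$feature_mz), seq_along(blank$feature_mz))
  o <- order(pool)
  cl <- gap_clusters(pool[o], tol_ppm)
  src <- src[o]; idx <- idx[o]

  drop <- logical(length(study$feature_mz))
  removed <- list()
  for (j in unique(cl)) {
    in_cl <- cl == j
    st <- idx[in_cl & src == "study"]
    bl <- idx[in_cl & src == "blank"]
    if (length(st) == 0L || length(bl) == 0L) next
    for (sf in st) {
      m_t <- med(study$values[, sf])
      m_b <- max(vapply(bl, function(bf) med(blank$values[, bf]), numeric(1)))
      if (m_t < fold * m_b) {
        drop[sf] <- TRUE
        removed[[length(removed) + 1L]] <- data.frame(
          feature_mz = study$feature_mz[sf], tissue_median = m_t,
          blank_median = m_b)
      }
    }
  }
  out <- subset_fm(study, features = which(!drop))
  attr(out, "background_removed") <-
    if (length(removed)) do.call(rbind, removed)
    else data.frame(feature_mz = numeric(0), tissue_median = numeric(0),
                    blank_median = numeric(0))
  out
}

#' Theoretical rhodamine 6G calibrant m/z
#'
#' The rhodamine 6G cation C28H31N2O3+ yields a single intense peak used
#' to monitor m/z drift. Without electron-mass correction the plain
#' elemental sum gives 443.2335 (the conventional printed value); with the
#' physically complete correction for the lost electron the value is
#' 443.2329.
#'
#' @param electron_correction Subtract the electron mass (default
#'   `FALSE`, matching the conventional value).
#' @return Calibrant m/z in Da.
#' @examples
#' round(rhodamine_6g_mz(), 4)
#' @export
rhodamine_6g_mz <- function(electron_correction = FALSE) {
  m <- monoisotopic_mass("C28H31N2O3")
  if (electron_correction) m - .ELECTRON_MASS else m
}

#' Monitor calibrant m/z drift
#'
#' @param observed_mz Measured calibrant m/z (Da).
#' @param theoretical_mz Theoretical calibrant m/z (default rhodamine 6G,
#'   443.2335).
#' @param limit_ppm Drift limit that triggers recalibration (default 25).
#' @return A list with `ppm_error` (signed) and `recalibrate` (logical,
#'   `TRUE` when |ppm| exceeds the limit).
#' @export
monitor_drift <- function(observed_mz, theoretical_mz = rhodamine_6g_mz(),
                          limit_ppm = 25) {
  if (any(observed_mz <= 0) || theoretical_mz <= 0)
    stop("m/z values must be positive", call. = FALSE)
  ppm <- (observed_mz - theoretical_mz) / theoretical_mz * 1e6
  list(ppm_error = ppm, recalibrate = abs(ppm) > limit_ppm)
}

#' Theoretical polyalanine [M+H]+ series
#'
#' Protonated polyalanine oligomers provide calibrant ions across the full
#' acquisition range: for n alanine residues,
#' `m/z = n * 71.03711 + 18.010565 + 1.007276` (residue + water + proton),
#' an arithmetic progression with spacing 71.03711 Da.
#'
#' @param n_min,n_max Residue count range (2 <= n_min <= n_max).
#' @param mz_range Restrict to this m/z window (default the acquisition
#'   range 50--1000 Da).
#' @return Named numeric vector of theoretical m/z values (names = residue
#'   counts).
#' @export
polyalanine_series <- function(n_min = 2, n_max = 13, mz_range = MZ_RANGE) {
  if (n_min < 2 || n_max < n_min)
    stop("invalid residue range: need 2 <= n_min <= n_max", call. = FALSE)
  n <- seq.int(n_min, n_max)
  mz <- n * 71.03711 + 18.010565 + 1.007276
  keep <- mz >= mz_range[1] & mz <= mz_range[2]
  stats::setNames(mz[keep], n[keep])
}

#' Fit a mass recalibration model from calibrant measurements
#'
#' Least-squares fit of the signed ppm error against m/z: either a
#' constant offset (`constant_ppm`) or a straight line in m/z
#' (`linear_in_mz`, requiring at least two distinct calibrant masses).
#'
#' @param observed Measured calibrant m/z values (Da).
#' @param theoretical Matching theoretical m/z values.
#' @param kind `"constant_ppm"` or `"linear_in_mz"`.
#' @return An object of class `calibration_model` with elements `kind`,
#'   `coefficients` and `fit_residual_ppm` (RMS of post-fit errors).
#' @export
fit_recalibration <- function(observed, theoretical,
                              kind = c("constant_ppm", "linear_in_mz")) {
  kind <- match.arg(kind)
  if (length(observed) != length(theoretical) || length(observed) == 0L)
    stop("need matched, non-empty calibrant vectors", call. = FALSE)
  ppm <- (observed - theoretical) / theoretical * 1e6
  if (kind == "constant_ppm") {
    coef <- c(intercept = mean(ppm))
    resid <- ppm - coef[[1]]
  } else {
    if (length(unique(theoretical)) < 2L)
      stop("linear recalibration needs >= 2 distinct calibrant masses",
           call. = FALSE)
    fit <- stats::lm.fit(cbind(1, theoretical), ppm)
    coef <- c(intercept = fit$coefficients[[1]], slope = fit$coefficients[[2]])
    resid <- fit$residuals
  }
  structure(list(kind = kind, coefficients = coef,
                 fit_residual_ppm = sqrt(mean(resid^2))),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s: %s (residual %.3f ppm)\n", x$kind,
              paste(sprintf("%s=%.4g", names(x$coefficients), x$coefficients),
                    collapse = ", "), x$fit_residual_ppm))
  invisible(x)
}

predict_ppm <- function(model, mz) {
  if (model$kind == "constant_ppm") rep(model$coefficients[[1]], length(mz))
  else model$coefficients[[1]] + model$coefficients[[2]] * mz
}

#' Apply a recalibration model to m/z values
#'
#' Multiplies every m/z by `1 - predicted_ppm * 1e-6`; applying the fitted
#' model to the calibrants reduces their absolute error to at most the
#' model's fit residual.
#'
#' @param model A `calibration_model` from [fit_recalibration()].
#' @param x A numeric vector of m/z values, a [feature_matrix] (its
#'   `feature_mz` is corrected), or an [msi_spectrum].
#' @return The corrected object, same class as `x`.
#' @export
apply_recalibration <- function(model, x) {
  corr <- function(mz) mz * (1 - predict_ppm(model, mz) * 1e-6)
  if (inherits(x, "feature_matrix")) {
    x$feature_mz <- corr(x$feature_mz)
    x
  } else if (inherits(x, "msi_spectrum")) {
    msi_spectrum(corr(x$mz), x$intensity, validate = FALSE)
  } else corr(x)
}
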