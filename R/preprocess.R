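# Per-section spectral cleanup, in the fixed order used throughout:
# SNR filter -> ppm alignment -> pixel-frequency filter -> RMS
# normalization. Each stage is exposed on its own; preprocess_section()
# runs the sequence and records an audit log.

#' Preprocessing parameters
#'
#' @param snr_min Minimum signal-to-noise ratio for a peak to be kept
#'   (default 3, the conventional limit of detection).
#' @param intra_tol_ppm Within-section alignment tolerance in parts per
#'   million (default 25).
#' @param min_pixel_frac Minimum fraction of a section's pixels a feature
#'   must be observed in (default 0.05; the boundary is strict, features in
#'   *less than* this fraction are removed).
#' @param mad_scale Multiplier applied to the median absolute deviation
#'   when estimating the noise level (default 1: plain MAD, no Gaussian
#'   consistency factor).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(snr_min = 3, intra_tol_ppm = 25,
                              min_pixel_frac = 0.05, mad_scale = 1) {
  stopifnot(snr_min > 0, intra_tol_ppm > 0,
            min_pixel_frac >= 0, min_pixel_frac < 1, mad_scale >= 0)
  structure(list(snr_min = snr_min, intra_tol_ppm = intra_tol_ppm,
                 min_pixel_frac = min_pixel_frac, mad_scale = mad_scale),
            class = "preprocess_params")
}

#' Estimate a spectrum's noise level
#'
#' The noise level is the (optionally scaled) median absolute deviation of
#' the peak intensities of the pixel's spectrum:
#' `mad_scale * median(|intensity - median(intensity)|)`.
#'
#' @param spectrum An [msi_spectrum] with at least one peak.
#' @param mad_scale MAD multiplier (default 1; 1.4826 would give the
#'   Gaussian-consistent estimate).
#' @return Noise level on the intensity scale.
#' @examples
#' estimate_noise(msi_spectrum(c(100, 200, 300, 400, 500), c(1, 2, 3, 4, 100)))
#' @export
estimate_noise <- function(spectrum, mad_scale = 1) {
  if (length(spectrum$intensity) == 0L)
    stop("cannot estimate noise of an empty pixel spectrum", call. = FALSE)
  stats::mad(spectrum$intensity, constant = mad_scale)
}

#' Remove low signal-to-noise peaks from a spectrum
#'
#' Keeps peaks with `intensity / noise >= snr_min`. A zero noise level
#' (constant or single-peak spectra) leaves the spectrum untouched: the
#' SNR is undefined and a degenerate spectrum must not be annihilated.
#'
#' @param spectrum An [msi_spectrum].
#' @param params A [preprocess_params] object.
#' @return The filtered [msi_spectrum] (possibly empty), m/z order
#'   preserved.
#' @export
snr_filter <- function(spectrum, params = preprocess_params()) {
  noise <- estimate_noise(spectrum, params$mad_scale)
  if (noise == 0) return(spectrum)
  keep <- spectrum$intensity / noise >= params$snr_min
  msi_spectrum(spectrum$mz[keep], spectrum$intensity[keep], validate = FALSE)
}

# Gap-rule single-linkage clustering of sorted m/z values: cut wherever the
# gap between consecutive values exceeds tol_ppm of the lower value.
# Returns integer cluster ids parallel to the *sorted* input.
gap_clusters <- function(mz_sorted, tol_ppm) {
  if (length(mz_sorted) <= 1L) return(rep(1L, length(mz_sorted)))
  gaps <- diff(mz_sorted) > tol_ppm * mz_sorted[-length(mz_sorted)] * 1e-6
  cumsum(c(1L, as.integer(gaps)))
}

#' Align peaks across the pixels of one section
#'
#' Pools every peak from every pixel, sorts by m/z, and cuts clusters
#' wherever the gap between consecutive pooled m/z values exceeds
#' `tol_ppm * (lower m/z) * 1e-6` (single-linkage gap rule; deterministic
#' and order-independent). The consensus feature m/z is the
#' intensity-weighted mean of the member peaks (plain mean with
#' `consensus = "mean"`). When a pixel contributes more than one peak to a
#' cluster the most intense is kept (ties broken toward lower m/z).
#'
#' @param section An [msi_section], or a bare list of [msi_spectrum]
#'   objects (pixels then get synthetic coordinates).
#' @param tol_ppm Alignment tolerance in ppm (default 25).
#' @param consensus `"weighted"` (intensity-weighted mean, default) or
#'   `"mean"`.
#' @param min_pixels Drop clusters supported by fewer than this many
#'   distinct pixels *before* materializing the matrix (default 1: keep
#'   everything). Equivalent to, but far cheaper than, building the full
#'   matrix and applying [pixel_frequency_filter()], since sparse noise
#'   peaks form vast numbers of singleton clusters.
#' @return A [feature_matrix] with one row per pixel; `NA` marks pixels
#'   that contributed no peak to a feature.
#' @export
align_section <- function(section, tol_ppm = 25,
                          consensus = c("weighted", "mean"),
                          min_pixels = 1L) {
  consensus <- match.arg(consensus)
  if (inherits(section, "msi_section")) {
    spectra <- section$spectra
    meta <- data.frame(section_id = section$section_id,
                       x = section$coords$x, y = section$coords$y,
                       time_point_h = section$time_point_h,
                       treatment = section$treatment)
    shapes <- stats::setNames(list(section$grid_shape), section$section_id)
  } else {
    spectra <- section
    meta <- data.frame(section_id = "section", x = seq_along(spectra), y = 1L,
                       time_point_h = NA_real_, treatment = NA_character_)
    shapes <- list(section = c(1L, length(spectra)))
  }
  npk <- vapply(spectra, function(s) length(s$mz), integer(1))
  if (sum(npk) == 0L)
    stop("all spectra in the section are empty; nothing to align", call. = FALSE)
  pool_mz <- unlist(lapply(spectra, `[[`, "mz"), use.names = FALSE)
  pool_int <- unlist(lapply(spectra, `[[`, "intensity"), use.names = FALSE)
  pool_px <- rep.int(seq_along(spectra), npk)

  o <- order(pool_mz)
  pool_mz <- pool_mz[o]; pool_int <- pool_int[o]; pool_px <- pool_px[o]
  cl <- gap_clusters(pool_mz, tol_ppm)
  if (min_pixels > 1L) {
    support <- rowsum(as.integer(!duplicated(cbind(cl, pool_px))), cl)
    keep_cl <- which(support >= min_pixels)
    if (length(keep_cl) == 0L)
      stop("no feature cluster reaches the pixel support threshold",
           call. = FALSE)
    sel <- cl %in% keep_cl
    pool_mz <- pool_mz[sel]; pool_int <- pool_int[sel]; pool_px <- pool_px[sel]
    cl <- match(cl[sel], keep_cl)
  }
  ncl <- cl[length(cl)]

  w <- if (consensus == "weighted") pool_int else rep(1, length(pool_int))
  # Guard against all-zero weights within a cluster.
  wsum <- rowsum(w, cl)
  w <- ifelse(rep(wsum[cl] > 0, 1), w, 1)
  centers <- as.vector(rowsum(pool_mz * w, cl) / rowsum(w, cl))

  # One value per (pixel, cluster): maximal intensity, ties to lower m/z.
  o2 <- order(cl, pool_px, -pool_int, pool_mz)
  first <- !duplicated(cbind(cl, pool_px)[o2, , drop = FALSE])
  sel <- o2[first]
  vals <- matrix(NA_real_, nrow = length(spectra), ncol = ncl)
  vals[cbind(pool_px[sel], cl[sel])] <- pool_int[sel]

  feature_matrix(centers, vals, meta, grid_shapes = shapes, validate = FALSE)
}

#' Remove features observed in too few pixels
#'
#' Drops features observed (non-missing) in fewer than
#' `ceiling(min_frac * n_pixels)` pixels of the section; the pixel set is
#' unchanged. The boundary is strict: a feature in exactly 5% of pixels
#' survives the default filter.
#'
#' @param fm A single-section [feature_matrix].
#' @param min_frac Minimum pixel fraction (default 0.05).
#' @return The filtered [feature_matrix].
#' @export
pixel_frequency_filter <- function(fm, min_frac = 0.05) {
  if (min_frac <= 0) return(fm)
  need <- ceiling(min_frac * nrow(fm$values))
  keep <- colSums(!is.na(fm$values)) >= need
  subset_fm(fm, features = which(keep))
}

#' RMS-normalize each pixel
#'
#' Divides each pixel's observed intensities by the root mean square of
#' that pixel's observed intensities; missing entries stay missing; after
#' normalization every pixel has RMS exactly 1. Zeros are never imputed
#' before normalization.
#'
#' @param fm A [feature_matrix] in which every pixel has at least one
#'   observed feature.
#' @return The normalized [feature_matrix].
#' @export
rms_normalize <- function(fm) {
  sq <- fm$values^2
  rms <- sqrt(rowMeans(sq, na.rm = TRUE))
  empty <- !is.finite(rms) | rms == 0
  if (any(empty)) {
    i <- which(empty)[1]
    stop(sprintf(
      "pixel(s) with no observed features cannot be RMS-normalized (first: %s x=%d y=%d; %d total)",
      fm$pixel_meta$section_id[i], fm$pixel_meta$x[i], fm$pixel_meta$y[i],
      sum(empty)), call. = FALSE)
  }
  fm$values <- fm$values / rms
  fm
}

#' Run the full per-section preprocessing sequence
#'
#' Applies, in order: SNR filtering of each pixel spectrum, within-section
#' ppm alignment, the pixel-frequency filter, and RMS normalization. The
#' returned audit log records the stage order and per-stage peak/feature
#' counts, and doubles as the per-section QC report.
#'
#' @param section An [msi_section].
#' @param params A [preprocess_params] object.
#' @return A list with elements `fm` (the [feature_matrix]) and `log`
#'   (data frame with columns `stage`, `n_pixels`, `n_features`,
#'   `n_peaks`).
#' @export
preprocess_section <- function(section, params = preprocess_params()) {
  n_peaks0 <- sum(vapply(section$spectra, function(s) length(s$mz), integer(1)))
  filtered <- lapply(section$spectra, snr_filter, params = params)
  n_peaks1 <- sum(vapply(filtered, function(s) length(s$mz), integer(1)))
  sec2 <- section
  sec2$spectra <- filtered

  # Clusters below the pixel-support threshold are pruned during
  # alignment (identical outcome to filtering afterwards, without
  # materializing columns for every sparse noise peak).
  fm <- align_section(sec2, tol_ppm = params$intra_tol_ppm,
                      min_pixels = max(1L, ceiling(params$min_pixel_frac *
                                                     length(sec2$spectra))))
  fm2 <- pixel_frequency_filter(fm, params$min_pixel_frac)
  # Pixels left with no observed feature after filtering (pure-noise
  # pixels) are dropped before normalization rather than erroring.
  observed <- rowSums(!is.na(fm2$values)) > 0
  if (!all(observed)) fm2 <- subset_fm(fm2, pixels = which(observed))
  fm3 <- rms_normalize(fm2)

  log <- data.frame(
    stage = c("input", "snr_filter", "align", "pixel_filter", "rms_normalize"),
    n_pixels = c(length(section$spectra), length(section$spectra),
                 nrow(fm$values), nrow(fm2$values), nrow(fm3$values)),
    n_features = c(NA, NA, ncol(fm$values), ncol(fm2$values), ncol(fm3$values)),
    n_peaks = c(n_peaks0, n_peaks1, sum(!is.na(fm$values)),
                sum(!is.na(fm2$values)), sum(!is.na(fm3$values))))
  list(fm = fm3, log = log)
}
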