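# Synthetic whole-body DESI-MSI study generator. Emulates the anatomical,
# temporal and exposure structure of a two-treatment, four-time-point,
# three-replicate whole-body study: region-specific PC/TG abundances, egg
# development trends, a 48 h BPA perturbation, ppm-scale m/z jitter with
# monotone acquisition drift, background ions shared with blank slides,
# and detection-threshold dropout as the missingness mechanism.

#' Default synthetic study specification
#'
#' Defines the phantom geometry (body, eye, gut, appendages, brood
#' chamber with six egg discs), a 20-lipid PC/TG panel emitted as single
#' adducts with pairwise spacing > 100 ppm, region x lipid base
#' abundances with region-specific signatures, egg-development
#' multipliers per lipid class, the 48 h BPA effect (PC x0.6, TG x1.5 in
#' eggs and storage sites, back to control at 72 h), a lognormal
#' intensity noise model with detection-threshold dropout, and background
#' ions (including the rhodamine 6G calibrant) present on every slide.
#'
#' @param grid_shape Integer `c(n_rows, n_cols)` (default `c(50, 80)`).
#' @param sigma_log_intensity Lognormal intensity noise sd on the log
#'   scale (default 0.3).
#' @param sigma_ppm Per-peak m/z jitter sd in ppm (default 5).
#' @param drift_ppm_per_section Monotone m/z drift per acquisition index
#'   in ppm (default 2).
#' @param detection_threshold Intensity below which a peak is not
#'   detected (default 40) -- the missingness mechanism.
#' @return An object of class `phantom_spec`.
#' @export
default_phantom_spec <- function(grid_shape = c(50, 80),
                                 sigma_log_intensity = 0.3,
                                 sigma_ppm = 5,
                                 drift_ppm_per_section = 2,
                                 detection_threshold = 40) {
  rois <- list(
    roi_ellipse("body", center = c(40, 26), semi_axes = c(32, 17),
                region = "tissue"),
    roi_ellipse("eye", center = c(15, 20), semi_axes = c(2.8, 2.8),
                parent = "body"),
    roi_ellipse("gut", center = c(38, 27), semi_axes = c(16, 3),
                parent = "body"),
    roi_ellipse("appendages", center = c(30, 37), semi_axes = c(11, 3.5),
                rotation = 0.2, parent = "body"),
    roi_ellipse("brood_chamber", center = c(54, 18), semi_axes = c(10, 6),
                parent = "body"),
    roi_ellipse("egg1", center = c(47, 18), semi_axes = c(2.3, 2.3),
                region = "eggs", parent = "brood_chamber"),
    roi_ellipse("egg2", center = c(51, 14.8), semi_axes = c(2.3, 2.3),
                region = "eggs", parent = "brood_chamber"),
    roi_ellipse("egg3", center = c(51, 21.2), semi_axes = c(2.3, 2.3),
                region = "eggs", parent = "brood_chamber"),
    roi_ellipse("egg4", center = c(55, 18), semi_axes = c(2.3, 2.3),
                region = "eggs", parent = "brood_chamber"),
    roi_ellipse("egg5", center = c(59, 15.5), semi_axes = c(2.3, 2.3),
                region = "eggs", parent = "brood_chamber"),
    roi_ellipse("egg6", center = c(59, 20.5), semi_axes = c(2.3, 2.3),
                region = "eggs", parent = "brood_chamber"))

  lib <- build_lipid_library()
  emit_adduct <- ifelse(lib$class == "PC", "[M+Na]+", "[M+K]+")
  emit_mz <- vapply(seq_len(nrow(lib)), function(i)
    adduct_mz(monoisotopic_mass(lib$formula[i]), emit_adduct[i]), numeric(1))
  panel <- data.frame(lib, adduct = emit_adduct, emit_mz = emit_mz)

  # Each region has a distinct lipidomic phenotype: phosphatidylcholines
  # accumulate in the eggs and eye, triacylglycerides in the appendages
  # and eggs, so the PC:TG ratio orders the tissues
  # (eye >> eggs > body > gut > appendages) and region-signature species
  # sharpen the separation further.
  regions <- c("tissue", "eye", "gut", "appendages", "brood_chamber", "eggs")
  base_by_class <- rbind(
    tissue = c(PC = 140, TG = 140),
    eye = c(PC = 700, TG = 60),
    gut = c(PC = 200, TG = 500),
    appendages = c(PC = 80, TG = 900),
    brood_chamber = c(PC = 170, TG = 160),
    eggs = c(PC = 900, TG = 450))
  abundance <- base_by_class[regions, panel$class]
  dimnames(abundance) <- list(regions, panel$name)
  boost <- function(region, lipids, f) abundance[region, lipids] <<-
    abundance[region, lipids] * f
  boost("eye", c("PC(38:4)", "PC(38:6)"), 3)
  boost("gut", c("TG(46:2)", "TG(48:2)"), 2.2)
  boost("gut", "PC(30:0)", 6)
  boost("appendages", c("TG(54:4)", "TG(54:6)"), 2)
  boost("eggs", c("PC(32:0)", "PC(34:3)"), 11 / 9)
  boost("eggs", c("TG(48:5)", "TG(50:6)"), 14 / 9)

  temporal <- rbind(PC = c(1, 1, 1.1, 1.8), TG = c(1, 0.85, 0.70, 0.55))
  colnames(temporal) <- c("8", "24", "48", "72")

  treatment_effects <- data.frame(
    time_point_h = 48, treatment = "BPA",
    region = c("eggs", "eye", "eggs", "appendages"),
    class = c("PC", "PC", "TG", "TG"),
    factor = c(0.6, 0.6, 1.5, 1.5))

  # Intense background ions (solvent clusters, dye, plasticizers) present
  # on every slide; kept at comparable magnitudes so that none falls below
  # a blank pixel's own SNR threshold.
  background_ions <- data.frame(
    mz = c(104.1075, 279.0937, 301.1410, 391.2843, 413.2662,
           rhodamine_6g_mz(), 663.4550),
    intensity = c(800, 900, 700, 1000, 650, 1500, 750))

  spec <- structure(list(
    grid_shape = as.integer(grid_shape), pixel_size_um = 35,
    rois = rois, panel = panel, abundance = abundance,
    temporal = temporal, treatment_effects = treatment_effects,
    noise = list(sigma_log_intensity = sigma_log_intensity,
                 sigma_ppm = sigma_ppm,
                 drift_ppm_per_section = drift_ppm_per_section,
                 detection_threshold = detection_threshold),
    # Dense low-intensity chemical-noise peaks present in every pixel
    # (tissue, off-tissue and blank alike): they carry the pixel's noise
    # floor, so the MAD noise estimate reflects noise rather than signal
    # spread, and they are what the SNR and pixel-frequency filters exist
    # to remove.
    noise_peaks = list(rate = 40, median_intensity = 55, sigma_log = 0.4),
    background_ions = background_ions), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks the panel's pairwise emission m/z separation (> 100 ppm), the
#' positivity of abundances and effect factors, and the ROI geometry.
#'
#' @param spec A `phantom_spec`.
#' @return The spec, invisibly; errors on violation.
#' @export
validate_phantom_spec <- function(spec) {
  mz <- sort(spec$panel$emit_mz)
  gap_ppm <- diff(mz) / mz[-length(mz)] * 1e6
  if (length(gap_ppm) && min(gap_ppm) <= 100)
    stop("panel emission m/z separation must exceed 100 ppm", call. = FALSE)
  if (any(spec$abundance <= 0)) stop("base abundances must be > 0", call. = FALSE)
  if (any(spec$temporal <= 0) || any(spec$treatment_effects$factor <= 0))
    stop("multiplicative factors must be > 0", call. = FALSE)
  if (any(spec$background_ions$intensity <= 0))
    stop("background intensities must be > 0", call. = FALSE)
  roi_depth(spec$rois)  # errors on missing parents / cycles
  invisible(spec)
}

# Region label per grid pixel (column-major over [row, col]): the
# annotation machinery itself is used, so ground-truth masks and pixel
# annotation agree by construction. NA = off-tissue.
phantom_region_labels <- function(spec) {
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  meta <- data.frame(section_id = "phantom",
                     x = rep(seq_len(nc), each = nr),
                     y = rep(seq_len(nr), times = nc))
  fm <- feature_matrix(1, matrix(1, nrow(meta), 1), meta,
                       grid_shapes = list(phantom = spec$grid_shape),
                       validate = FALSE)
  ann <- annotate_pixels(fm, spec$rois)
  lab <- rep(NA_character_, nrow(meta))
  idx <- (ann$pixel_meta$x - 1L) * nr + ann$pixel_meta$y
  lab[idx] <- ann$pixel_meta$region_label
  lab
}

# Ensure strictly increasing m/z within each pixel (collisions between
# random noise peaks are possible in principle).
.fix_monotone <- function(mz) {
  if (length(mz) > 1L) {
    for (i in 2:length(mz)) if (mz[i] <= mz[i - 1]) mz[i] <- mz[i - 1] + 1e-6
  }
  mz
}

#' Simulate one tissue section
#'
#' Per tissue pixel and panel lipid the true intensity is
#' `base(region) x temporal(time, class) x treatment factor`; the
#' observed intensity multiplies in lognormal noise, and the observed m/z
#' applies the acquisition drift plus Gaussian ppm jitter. Peaks below
#' the detection threshold are dropped (the missingness mechanism).
#' Background ions are added to every pixel; off-tissue pixels carry only
#' background plus sparse noise peaks. Deterministic for a fixed seed.
#'
#' @param spec A [default_phantom_spec()] object.
#' @param time_point_h One of 8, 24, 48, 72.
#' @param treatment `"control"` or `"BPA"`.
#' @param replicate Replicate number (used in ids).
#' @param acquisition_index Position in the acquisition order (drives the
#'   drift).
#' @param seed RNG seed.
#' @param section_id Identifier (default built from the design cell).
#' @return List with `section` (an [msi_section]) and `truth` (region
#'   labels per pixel, per-pixel true intensities per lipid, applied
#'   drift and effect factors).
#' @export
simulate_section <- function(spec, time_point_h, treatment, replicate = 1,
                             acquisition_index = 0, seed = 1,
                             section_id = NULL) {
  if (!time_point_h %in% c(8, 24, 48, 72))
    stop("invalid time point", call. = FALSE)
  if (!treatment %in% c("control", "BPA"))
    stop("invalid treatment", call. = FALSE)
  if (is.null(section_id))
    section_id <- sprintf("s_%s_%02dh_r%d", treatment, time_point_h, replicate)
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  npx <- nr * nc
  labels <- phantom_region_labels(spec)
  tissue_px <- which(!is.na(labels))
  panel <- spec$panel
  nl <- nrow(panel)
  drift <- spec$noise$drift_ppm_per_section * acquisition_index

  # True intensities: tissue pixels x lipids.
  true_int <- spec$abundance[labels[tissue_px], , drop = FALSE]
  tcol <- as.character(time_point_h)
  egg_rows <- labels[tissue_px] == "eggs"
  for (cls in rownames(spec$temporal)) {
    cols <- which(panel$class == cls)
    true_int[egg_rows, cols] <- true_int[egg_rows, cols] *
      spec$temporal[cls, tcol]
  }
  eff <- spec$treatment_effects
  eff <- eff[eff$time_point_h == time_point_h & eff$treatment == treatment, ,
             drop = FALSE]
  applied_effects <- eff
  if (nrow(eff)) {
    for (i in seq_len(nrow(eff))) {
      rws <- labels[tissue_px] == eff$region[i]
      cols <- which(panel$class == eff$class[i])
      true_int[rws, cols] <- true_int[rws, cols] * eff$factor[i]
    }
  }

  with_seed(seed, {
    obs_int <- true_int * matrix(
      stats::rlnorm(length(true_int), 0, spec$noise$sigma_log_intensity),
      nrow = nrow(true_int))
    keep <- obs_int >= spec$noise$detection_threshold
    kidx <- which(keep, arr.ind = TRUE)
    panel_px <- tissue_px[kidx[, 1]]
    panel_mz <- panel$emit_mz[kidx[, 2]] *
      (1 + (drift + stats::rnorm(nrow(kidx), 0, spec$noise$sigma_ppm)) * 1e-6)
    panel_int <- obs_int[keep]

    nb <- nrow(spec$background_ions)
    bg_px <- rep(seq_len(npx), each = nb)
    bg_int <- rep(spec$background_ions$intensity, times = npx) *
      stats::rlnorm(npx * nb, 0, spec$noise$sigma_log_intensity)
    bg_mz <- rep(spec$background_ions$mz, times = npx) *
      (1 + (drift + stats::rnorm(npx * nb, 0, spec$noise$sigma_ppm)) * 1e-6)
    bg_keep <- bg_int >= spec$noise$detection_threshold

    n_noise <- stats::rpois(npx, spec$noise_peaks$rate)
    nz_px <- rep(seq_len(npx), n_noise)
    nz_mz <- stats::runif(length(nz_px), MZ_RANGE[1] + 1, MZ_RANGE[2] - 1)
    nz_int <- spec$noise_peaks$median_intensity *
      stats::rlnorm(length(nz_px), 0, spec$noise_peaks$sigma_log)
    nz_keep <- nz_int >= spec$noise$detection_threshold

    all_px <- c(panel_px, bg_px[bg_keep], nz_px[nz_keep])
    all_mz <- c(panel_mz, bg_mz[bg_keep], nz_mz[nz_keep])
    all_int <- c(panel_int, bg_int[bg_keep], nz_int[nz_keep])
  })

  o <- order(all_px, all_mz)
  all_px <- all_px[o]; all_mz <- all_mz[o]; all_int <- all_int[o]
  f <- factor(all_px, levels = seq_len(npx))
  mz_by_px <- split(all_mz, f)
  int_by_px <- split(all_int, f)
  spectra <- lapply(seq_len(npx), function(i)
    msi_spectrum(.fix_monotone(mz_by_px[[i]]), int_by_px[[i]],
                 validate = FALSE))

  coords <- data.frame(x = rep(seq_len(nc), each = nr),
                       y = rep(seq_len(nr), times = nc))
  section <- msi_section(
    spectra, coords, spec$grid_shape, section_id,
    pixel_size_um = spec$pixel_size_um,
    subject_id = sprintf("daphnid_%s_%02dh_r%d", treatment, time_point_h,
                         replicate),
    time_point_h = time_point_h, treatment = treatment,
    acquisition_index = acquisition_index)
  truth <- list(section_id = section_id, region_label = labels,
                coords = coords, tissue_pixels = tissue_px,
                true_intensity = true_int, panel = panel,
                drift_ppm = drift, effects = applied_effects,
                rois = spec$rois)
  list(section = section, truth = truth)
}

#' Simulate a blank DESI slide
#'
#' All pixels carry the background ions (with intensity noise and m/z
#' jitter/drift) and no panel lipids.
#'
#' @param spec A [default_phantom_spec()] object.
#' @param seed RNG seed.
#' @param acquisition_index Position in the acquisition order.
#' @param section_id Identifier (default `"blank"`).
#' @return An [msi_section] with `is_blank = TRUE`.
#' @export
simulate_blank <- function(spec, seed = 1, acquisition_index = 0,
                           section_id = "blank") {
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  npx <- nr * nc
  nb <- nrow(spec$background_ions)
  drift <- spec$noise$drift_ppm_per_section * acquisition_index
  with_seed(seed, {
    px <- rep(seq_len(npx), each = nb)
    int <- rep(spec$background_ions$intensity, times = npx) *
      stats::rlnorm(npx * nb, 0, spec$noise$sigma_log_intensity)
    mz <- rep(spec$background_ions$mz, times = npx) *
      (1 + (drift + stats::rnorm(npx * nb, 0, spec$noise$sigma_ppm)) * 1e-6)
    n_noise <- stats::rpois(npx, spec$noise_peaks$rate)
    nz_px <- rep(seq_len(npx), n_noise)
    nz_mz <- stats::runif(length(nz_px), MZ_RANGE[1] + 1, MZ_RANGE[2] - 1)
    nz_int <- spec$noise_peaks$median_intensity *
      stats::rlnorm(length(nz_px), 0, spec$noise_peaks$sigma_log)
  })
  px <- c(px, nz_px); mz <- c(mz, nz_mz); int <- c(int, nz_int)
  keep <- int >= spec$noise$detection_threshold
  px <- px[keep]; mz <- mz[keep]; int <- int[keep]
  o <- order(px, mz)
  f <- factor(px[o], levels = seq_len(npx))
  mz_by_px <- split(mz[o], f)
  int_by_px <- split(int[o], f)
  spectra <- lapply(seq_len(npx), function(i)
    msi_spectrum(.fix_monotone(mz_by_px[[i]]), int_by_px[[i]],
                 validate = FALSE))
  coords <- data.frame(x = rep(seq_len(nc), each = nr),
                       y = rep(seq_len(nr), times = nc))
  msi_section(spectra, coords, spec$grid_shape, section_id,
              pixel_size_um = spec$pixel_size_um,
              acquisition_index = acquisition_index, is_blank = TRUE)
}

#' Simulate the full study
#'
#' 2 treatments x 4 time points x 3 replicates = 24 tissue sections plus
#' blank slides at the start and end of acquisition. The acquisition
#' order is block-randomized: each (time point, replicate) pair forms a
#' block containing both treatments, block order and within-block order
#' are shuffled, so every block is balanced over treatment while the
#' monotone m/z drift accumulates over the acquisition index.
#'
#' @param spec A [default_phantom_spec()] object.
#' @param seed Root RNG seed; all per-section seeds derive from it.
#' @param dir When non-`NULL`, writes the study to disk: one imzML/ibd
#'   pair per section, `manifest.yaml`, `rois.yaml` and ground-truth
#'   tables (`truth_regions.tsv`, `truth_effects.tsv`,
#'   `truth_drift.tsv`), so the full pipeline can run with no other
#'   input.
#' @return A list: `sections` (24 tissue [msi_section]s), `blanks` (2),
#'   `manifest` (data frame), `rois`, `truth` (per-section ground truth),
#'   `spec`.
#' @export
simulate_study <- function(spec, seed = 1, dir = NULL) {
  design <- expand.grid(replicate = 1:3, time_point_h = c(8, 24, 48, 72),
                        treatment = c("control", "BPA"),
                        stringsAsFactors = FALSE)
  blocks <- split(seq_len(nrow(design)),
                  paste(design$time_point_h, design$replicate))
  order_idx <- with_seed(seed, {
    unlist(lapply(sample(blocks), sample), use.names = FALSE)
  })
  design <- design[order_idx, , drop = FALSE]
  design$acquisition_index <- seq_len(nrow(design))

  sections <- vector("list", nrow(design))
  truth <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    si <- (seed * 97L + i * 1009L) %% 2147483647L
    sim <- simulate_section(spec, design$time_point_h[i],
                            design$treatment[i], design$replicate[i],
                            acquisition_index = design$acquisition_index[i],
                            seed = si)
    sections[[i]] <- sim$section
    truth[[i]] <- sim$truth
  }
  names(sections) <- vapply(sections, `[[`, character(1), "section_id")
  names(truth) <- names(sections)
  blanks <- list(
    simulate_blank(spec, seed = (seed * 97L + 25031L) %% 2147483647L,
                   acquisition_index = 0, section_id = "blank_start"),
    simulate_blank(spec, seed = (seed * 97L + 26003L) %% 2147483647L,
                   acquisition_index = nrow(design) + 1L,
                   section_id = "blank_end"))
  names(blanks) <- c("blank_start", "blank_end")

  all_secs <- c(sections, blanks)
  manifest <- do.call(rbind, lapply(all_secs, function(s) data.frame(
    section_id = s$section_id,
    file = paste0(s$section_id, ".imzML"),
    subject_id = s$subject_id, time_point_h = s$time_point_h,
    treatment = s$treatment, acquisition_index = s$acquisition_index,
    is_blank = s$is_blank)))
  rownames(manifest) <- NULL

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in all_secs) write_imzml(s, file.path(dir, paste0(s$section_id, ".imzML")))
    write_manifest(manifest, file.path(dir, "manifest.yaml"))
    write_roi_config(spec$rois, file.path(dir, "rois.yaml"))
    lab <- truth[[1]]$region_label
    utils::write.table(
      data.frame(truth[[1]]$coords,
                 region_label = ifelse(is.na(lab), "", lab)),
      file.path(dir, "truth_regions.tsv"), sep = "\t", row.names = FALSE)
    utils::write.table(spec$treatment_effects,
                       file.path(dir, "truth_effects.tsv"), sep = "\t",
                       row.names = FALSE)
    utils::write.table(
      data.frame(section_id = manifest$section_id,
                 acquisition_index = manifest$acquisition_index,
                 drift_ppm = spec$noise$drift_ppm_per_section *
                   manifest$acquisition_index),
      file.path(dir, "truth_drift.tsv"), sep = "\t", row.names = FALSE)
  }
  list(sections = sections, blanks = blanks, manifest = manifest,
       rois = spec$rois, truth = truth, spec = spec)
}
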