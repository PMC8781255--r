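# Config-driven orchestration of the end-to-end workflow: read ->
# per-section preprocessing -> calibrant recalibration -> study alignment
# -> blank background removal -> ROI annotation -> mode-specific
# statistics -> MS1 annotation -> ion images, with a run log and a
# machine-readable summary.

#' Assemble a pipeline configuration
#'
#' @param manifest Path to a study manifest (YAML) or an in-memory study
#'   bundle from [simulate_study()].
#' @param roi_config Path to a ROI YAML or a list of [roi] objects.
#' @param mode `"tissue_types"`, `"egg_timecourse"` or
#'   `"exposure_contrast"`.
#' @param preprocess A [preprocess_params] object.
#' @param stats A [stats_params] object.
#' @param lipid_library Library data frame or TSV path (default the
#'   packaged library).
#' @param study_tol_ppm Study-level alignment tolerance (default 35).
#' @param background_fold Blank-removal fold threshold (default 10).
#' @param recalibrate Recalibrate each section's m/z axis against the
#'   rhodamine 6G calibrant ion before study alignment (default `TRUE`).
#' @param target_time_h Time point for the exposure contrast (default 48).
#' @param ion_image_mz m/z values to image (default the four headline
#'   lipids' emitted adduct ions).
#' @param out_dir Output directory, or `NULL` for no file output.
#' @param seed Root seed for all stochastic steps.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, roi_config,
                            mode = c("tissue_types", "egg_timecourse",
                                     "exposure_contrast"),
                            preprocess = preprocess_params(),
                            stats = stats_params(),
                            lipid_library = NULL,
                            study_tol_ppm = 35, background_fold = 10,
                            recalibrate = TRUE, target_time_h = 48,
                            ion_image_mz = NULL, out_dir = NULL, seed = 1L) {
  structure(list(manifest = manifest, roi_config = roi_config,
                 mode = match.arg(mode), preprocess = preprocess,
                 stats = stats, lipid_library = lipid_library,
                 study_tol_ppm = study_tol_ppm,
                 background_fold = background_fold,
                 recalibrate = recalibrate, target_time_h = target_time_h,
                 ion_image_mz = ion_image_mz, out_dir = out_dir,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Run the end-to-end workflow
#'
#' Executes the full processing sequence on a study and returns (and
#' optionally writes) the stage outputs: the study feature matrix, PCA
#' scores/loadings/variance, feature test tables, per-section medians,
#' MS1 annotations, QC log and a run summary. Any stage failure aborts
#' with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `study`
#'   (annotated [feature_matrix]), `pca`, `scores` (data frame with
#'   group labels), `tests` (exposure mode), `medians`
#'   (timecourse/exposure modes), `annotations`, `qc`, `log`, `summary`.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  note("daphmsi pipeline, seed %d, mode %s", config$seed, config$mode)

  secs <- stage("read", {
    if (is.character(config$manifest)) load_study(config$manifest)
    else c(config$manifest$sections, config$manifest$blanks)
  })
  is_blank <- vapply(secs, `[[`, logical(1), "is_blank")
  note("read %d sections (%d blanks)", length(secs), sum(is_blank))

  pp <- stage("preprocess", lapply(secs, preprocess_section,
                                   params = config$preprocess))
  fms <- lapply(pp, `[[`, "fm")
  qc_rows <- list()

  if (config$recalibrate) {
    rho <- rhodamine_6g_mz()
    fms <- stage("recalibrate", lapply(seq_along(fms), function(i) {
      fm <- fms[[i]]
      rel <- abs(fm$feature_mz - rho) / rho * 1e6
      j <- which.min(rel)
      if (length(j) == 0L || rel[j] > 100) {
        qc_rows[[length(qc_rows) + 1L]] <<- data.frame(
          section_id = names(fms)[i], calibrant_ppm = NA_real_,
          recalibrated = FALSE, residual_ppm = NA_real_)
        return(fm)
      }
      dr <- monitor_drift(fm$feature_mz[j], rho)
      model <- fit_recalibration(fm$feature_mz[j], rho, "constant_ppm")
      fm2 <- apply_recalibration(model, fm)
      qc_rows[[length(qc_rows) + 1L]] <<- data.frame(
        section_id = names(fms)[i], calibrant_ppm = dr$ppm_error,
        recalibrated = TRUE, residual_ppm = model$fit_residual_ppm)
      fm2
    }))
    names(fms) <- names(secs)
  }
  qc <- if (length(qc_rows)) do.call(rbind, qc_rows) else NULL

  study <- stage("study_alignment",
                 align_study(fms[!is_blank], tol_ppm = config$study_tol_ppm))
  note("study matrix: %d pixels x %d features", nrow(study$values),
       ncol(study$values))

  blank_fm <- stage("blank_pooling", {
    if (any(is_blank)) align_study(fms[is_blank],
                                   tol_ppm = config$study_tol_ppm)
    else NULL
  })
  if (!is.null(blank_fm)) {
    study <- stage("background_removal",
                   remove_background(study, blank_fm,
                                     fold = config$background_fold,
                                     tol_ppm = config$study_tol_ppm))
    note("background removal: %d features removed, %d kept",
         nrow(attr(study, "background_removed")), ncol(study$values))
  }

  rois <- stage("roi_annotation", {
    r <- if (is.character(config$roi_config)) read_roi_config(config$roi_config)
    else config$roi_config
    annotate_pixels(study, r)
  })
  study <- rois
  note("after ROI annotation: %d tissue pixels", nrow(study$values))

  sp <- config$stats
  result <- list(study = study, qc = qc)

  if (config$mode == "tissue_types") {
    sub <- stage("tissue_types", {
      keep <- study$pixel_meta$region_label %in%
        c("appendages", "eggs", "eye", "gut")
      subset_fm(study, pixels = which(keep))
    })
    sub <- stage("balanced_sampling",
                 balanced_sample(sub, "region_label", sp$n_per_group,
                                 seed = config$seed))
    sub <- stage("group_filters",
                 group_filters(sub, "region_label", sp$group_presence_frac,
                               sp$pixel_missing_frac))
    sub <- stage("ellipse_filter",
                 ellipse_outlier_filter(sub, "region_label",
                                        conf = sp$ellipse_conf, k = sp$knn_k))
    x <- stage("impute_scale", pareto_scale(knn_impute(sub$values, sp$knn_k)))
    pca <- stage("pca", pca_features(x, n_components = min(5, min(dim(x)))))
    scores <- data.frame(sub$pixel_meta,
                         PC1 = pca$scores[, 1], PC2 = pca$scores[, 2])
    # nearest group centroid in PC1-PC2
    cent <- stats::aggregate(scores[, c("PC1", "PC2")],
                             list(region = scores$region_label), mean)
    d2 <- outer(scores$PC1, cent$PC1, `-`)^2 + outer(scores$PC2, cent$PC2, `-`)^2
    assigned <- cent$region[apply(d2, 1, which.min)]
    acc <- mean(assigned == scores$region_label)
    note("tissue-type PCA: PC1 %.1f%%, PC2 %.1f%%; centroid assignment %.1f%%",
         100 * pca$var_explained[1], 100 * pca$var_explained[2], 100 * acc)
    result <- c(result, list(pca = pca, scores = scores,
                             region_assignment_accuracy = acc,
                             subset = sub))
  } else if (config$mode == "egg_timecourse") {
    sub <- stage("egg_subset", {
      keep <- study$pixel_meta$region_label == "eggs" &
        study$pixel_meta$treatment == "control"
      subset_fm(study, pixels = which(keep))
    })
    sub <- stage("group_filters", {
      sub$pixel_meta$time_label <- as.character(sub$pixel_meta$time_point_h)
      group_filters(sub, "time_label", sp$group_presence_frac,
                    sp$pixel_missing_frac)
    })
    sub <- stage("ellipse_filter",
                 ellipse_outlier_filter(sub, "time_label",
                                        conf = sp$ellipse_conf, k = sp$knn_k))
    x <- stage("impute_scale", pareto_scale(knn_impute(sub$values, sp$knn_k)))
    pca <- stage("pca", pca_features(x, n_components = min(5, min(dim(x)))))
    med <- stage("medians", median_by_section(study, region = "eggs"))
    scores <- data.frame(sub$pixel_meta,
                         PC1 = pca$scores[, 1], PC2 = pca$scores[, 2])
    note("egg timecourse: %d egg pixels, PC1 %.1f%%", nrow(sub$values),
         100 * pca$var_explained[1])
    result <- c(result, list(pca = pca, scores = scores, medians = med,
                             subset = sub))
  } else {  # exposure_contrast
    sub <- stage("egg_subset", {
      keep <- study$pixel_meta$region_label == "eggs" &
        study$pixel_meta$time_point_h == config$target_time_h
      subset_fm(study, pixels = which(keep))
    })
    sub <- stage("group_filters",
                 group_filters(sub, "treatment", sp$group_presence_frac,
                               sp$pixel_missing_frac))
    sub <- stage("ellipse_filter",
                 ellipse_outlier_filter(sub, "treatment",
                                        conf = sp$ellipse_conf, k = sp$knn_k))
    tests <- stage("feature_tests",
                   test_features(sub, "treatment", ref = "control",
                                 alt = "BPA", mode = "pixel_rank_sum"))
    x <- stage("impute_scale", pareto_scale(knn_impute(sub$values, sp$knn_k)))
    pca <- stage("pca", pca_features(x, n_components = min(5, min(dim(x)))))
    med <- stage("medians", median_by_section(study, region = "eggs"))
    scores <- data.frame(sub$pixel_meta,
                         PC1 = pca$scores[, 1], PC2 = pca$scores[, 2])
    note("exposure contrast at %g h: %d egg pixels, %d/%d features FDR<0.05",
         config$target_time_h, nrow(sub$values),
         sum(tests$fdr_adjusted_p < 0.05, na.rm = TRUE), nrow(tests))
    result <- c(result, list(pca = pca, scores = scores, tests = tests,
                             medians = med, subset = sub))
  }

  lib <- stage("annotation_library", {
    if (is.null(config$lipid_library)) default_lipid_library()
    else if (is.character(config$lipid_library))
      read_lipid_library(config$lipid_library)
    else config$lipid_library
  })
  ann <- stage("annotation",
               annotate_features(study$feature_mz, lib, tol_ppm = 25))
  note("annotation: %d of %d features annotated",
       length(unique(ann$feature_mz)), length(study$feature_mz))
  result$annotations <- ann

  img_mz <- config$ion_image_mz
  if (is.null(img_mz)) {
    four <- c("PC(32:0)", "PC(34:3)", "TG(48:5)", "TG(50:6)")
    best <- ann[ann$best & ann$name %in% four, , drop = FALSE]
    img_mz <- stats::setNames(best$feature_mz, best$name)
  }
  images <- stage("ion_images", {
    sec1 <- study$pixel_meta$section_id[1]
    common_scale(lapply(img_mz, function(m)
      ion_image(study, sec1, m, tol_ppm = config$study_tol_ppm)))
  })
  result$images <- images

  result$log <- log_lines
  result$summary <- list(
    mode = config$mode, seed = config$seed,
    n_sections = length(secs), n_blanks = sum(is_blank),
    n_pixels = nrow(study$values), n_features = ncol(study$values),
    n_annotated = length(unique(ann$feature_mz)))
  if (config$mode == "tissue_types")
    result$summary$region_assignment_accuracy <- result$region_assignment_accuracy
  if (config$mode == "exposure_contrast")
    result$summary$n_significant <- sum(result$tests$fdr_adjusted_p < 0.05,
                                        na.rm = TRUE)

  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) utils::write.table(
      x, file.path(od, f), sep = "\t", row.names = FALSE, quote = FALSE)
    wt(data.frame(feature_mz = study$feature_mz), "features.tsv")
    if (!is.null(result$scores)) wt(result$scores, "scores.tsv")
    if (!is.null(result$pca)) {
      wt(data.frame(feature_mz = result$subset$feature_mz,
                    result$pca$loadings[, 1:2, drop = FALSE]), "loadings.tsv")
      wt(data.frame(component = seq_along(result$pca$var_explained),
                    var_explained = result$pca$var_explained), "variance.tsv")
    }
    if (!is.null(result$tests)) wt(result$tests, "tests.tsv")
    if (!is.null(result$medians)) {
      med_df <- data.frame(attr(result$medians, "meta"),
                           result$medians, check.names = FALSE)
      wt(med_df, "medians.tsv")
    }
    wt(ann, "annotations.tsv")
    if (!is.null(qc)) wt(qc, "qc_log.tsv")
    for (nm in names(images))
      render_ion_image(images[[nm]],
                       file.path(od, paste0("ion_", gsub("[^A-Za-z0-9]", "",
                                                         nm), ".png")))
    writeLines(log_lines, file.path(od, "run_log.txt"))
    jsonlite::write_json(result$summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(result) <- "pipeline_result"
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}
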