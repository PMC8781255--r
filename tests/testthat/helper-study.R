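# The default synthetic study, simulated and pushed through the pipeline
# once per test session and shared across test files (several end-to-end
# properties are checked against the same run).

.daphmsi_cache <- new.env(parent = emptyenv())

study_seed <- function() 101L

default_study <- function() {
  if (is.null(.daphmsi_cache$study)) {
    dir <- file.path(tempdir(), "daphmsi-study")
    spec <- default_phantom_spec()
    bundle <- simulate_study(spec, seed = study_seed(), dir = dir)
    .daphmsi_cache$study <- list(spec = spec, bundle = bundle, dir = dir)
  }
  .daphmsi_cache$study
}

study_pipeline <- function(mode) {
  key <- paste0("run_", mode)
  if (is.null(.daphmsi_cache[[key]])) {
    st <- default_study()
    cfg <- pipeline_config(file.path(st$dir, "manifest.yaml"),
                           file.path(st$dir, "rois.yaml"),
                           mode = mode, seed = study_seed())
    .daphmsi_cache[[key]] <- run_pipeline(cfg)
  }
  .daphmsi_cache[[key]]
}

# The same study design with every injected effect switched off
# (temporal and treatment factors all 1): the null for false-positive
# rate checks. Run in memory (no file round trip needed for the null).
null_exposure_run <- function() {
  if (is.null(.daphmsi_cache$null_run)) {
    spec <- default_phantom_spec()
    spec$temporal[] <- 1
    spec$treatment_effects$factor <- 1
    bundle <- simulate_study(spec, seed = study_seed() + 1L)
    cfg <- pipeline_config(bundle, spec$rois, mode = "exposure_contrast",
                           seed = study_seed() + 1L)
    .daphmsi_cache$null_run <- run_pipeline(cfg)
  }
  .daphmsi_cache$null_run
}

# Mean observed ppm shift of a section's emitted ions (panel +
# background; intense peaks only, excluding the chemical-noise floor)
# against their emission m/z.
section_mean_ppm_shift <- function(section, spec) {
  emits <- sort(c(spec$panel$emit_mz, spec$background_ions$mz))
  mz <- unlist(lapply(section$spectra, `[[`, "mz"))
  int <- unlist(lapply(section$spectra, `[[`, "intensity"))
  mz <- mz[int > 300]
  i1 <- pmin(pmax(findInterval(mz, emits), 1), length(emits))
  i2 <- pmin(i1 + 1, length(emits))
  idx <- ifelse(abs(mz - emits[i1]) <= abs(mz - emits[i2]), i1, i2)
  ok <- abs(mz - emits[idx]) < 0.2
  mean((mz[ok] - emits[idx[ok]]) / emits[idx[ok]] * 1e6)
}

# True panel lipid for a study feature m/z: nearest emitted adduct ion.
true_panel_match <- function(feature_mz, panel) {
  idx <- vapply(feature_mz, function(m) which.min(abs(panel$emit_mz - m)),
                integer(1))
  data.frame(name = panel$name[idx],
             ppm = (feature_mz - panel$emit_mz[idx]) /
               panel$emit_mz[idx] * 1e6)
}
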