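# daphmsi

Processing and statistics for whole-body DESI mass spectrometry imaging
(DESI-MSI) of *Daphnia magna*, from imzML files to region-resolved
spatial lipidomics.

Whole-body homogenate lipidomics of daphnids averages away where in the
animal a toxicant acts. DESI-MSI records an untargeted mass spectrum at
every 35 µm pixel of a cryosection, so the lipidomes of individual
anatomical regions — developing eggs, eye, gut, appendages — can be
analysed separately. This package implements the complete data-analysis
workflow for such a study and a synthetic whole-body phantom that makes
every stage testable without the (very large) raw imaging data:

* **msi_core** — processed-mode imzML 1.1 reading/writing
  (`read_imzml`, `write_imzml`), the spectrum/section/feature-matrix
  data model, and the sidecar study manifest.
* **preprocess** — per-section cleanup in fixed order: MAD-based SNR
  filter (SNR < 3 removed), 25 ppm single-linkage gap alignment, 5%
  pixel-frequency filter, RMS normalization.
* **study_assembly** — 35 ppm cross-section alignment, removal of
  features under 10× the blank-slide median, rhodamine 6G drift
  monitoring (m/z 443.2335, 25 ppm limit) and polyalanine-based mass
  recalibration.
* **roi_annotation** — declarative ellipse/polygon ROIs with nesting
  (brood chamber → eggs), boundary-inclusive interior tests, background
  pixel removal.
* **feature_stats** — balanced sampling (200 pixels/group), per-group
  50% presence and 50% pixel-missingness filters, 95% confidence-ellipse
  outlier removal on PC1–PC2, KNN imputation (k = 5), pareto scaling,
  PCA, per-section medians, Mann–Whitney / signed-rank tests with
  Benjamini–Hochberg FDR.
* **lipid_annotation** — monoisotopic masses, the four positive DESI
  adducts, 25 ppm MS1 matching against a PC/TG library.
* **ion_imaging** — per-lipid intensity maps, common-intensity-scale
  series, deterministic viridis PNG rendering.
* **synthetic_daphnia** — the phantom study generator
  (2 treatments × 4 time points × 3 replicates + 2 blanks) with
  exported ground truth.
* **pipeline** — `run_pipeline()` orchestrates the whole sequence from
  a manifest + ROI config, in one of three modes: `tissue_types`,
  `egg_timecourse`, `exposure_contrast`.

The statistical model in brief: per pixel *p* and consensus feature
*f*, observed intensities are RMS-normalized
(x_pf / sqrt(mean_f x_pf²)); pixel phenotypes are compared by PCA of
pareto-scaled ((x − x̄)/√s) imputed matrices; exposure effects are
tested per feature by the rank-sum statistic on egg pixels with
step-up FDR control (adj p_(i) = min_{j≥i} m·p_(j)/j).

## Worked example

The numbered scripts under `analysis/` run the full study end to end
(each writes its tables under `results/`):

```sh
Rscript analysis/01_simulate_study.R     # 26 imzML files + manifest + ROIs
Rscript analysis/02_tissue_types.R       # balanced PCA of 4 tissue types
Rscript analysis/03_egg_development.R    # control egg time course
Rscript analysis/04_bpa_exposure.R       # BPA vs control at 48 h
Rscript analysis/05_qc_drift.R           # calibrant drift recovery
```

`analysis/02_tissue_types.R` prints (seed 1):

```
  read 26 sections (2 blanks)
  study matrix: 96000 pixels x 27 features
  background removal: 7 features removed, 20 kept
  after ROI annotation: 40872 tissue pixels
  tissue-type PCA: PC1 57.5%, PC2 14.1%; centroid assignment 93.4%
  annotation: 20 of 20 features annotated
```

meaning: all 27 study-level consensus features were found, the 7
injected background ions (solvent clusters plus the rhodamine
calibrant) were removed by the 10× blank rule, the 20 panel lipids were
all annotated correctly at 25 ppm after per-section recalibration, and
93% of the balanced-sampled pixels fall nearest their own tissue's
centroid in the PC1–PC2 plane — appendages, eggs, eye and gut carry
separable lipid phenotypes.

`analysis/04_bpa_exposure.R` reports every panel lipid significant at
FDR < 0.05 in the 48 h egg-pixel contrast, phosphatidylcholines down
and triacylglycerides up under BPA — the injected perturbation, with
its signs, recovered against the developmental trend.

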