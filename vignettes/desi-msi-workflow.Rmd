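---
title: "Processing and statistics for whole-body DESI-MSI lipidomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing and statistics for whole-body DESI-MSI lipidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daphmsi)
```

## The problem

Desorption electrospray ionization mass spectrometry imaging (DESI-MSI)
acquires an untargeted mass spectrum at every pixel of a tissue surface.
Applied to whole-body cryosections of *Daphnia magna* (a ~3 mm sentinel
crustacean used throughout regulatory ecotoxicology), it resolves the
lipidomes of individual anatomical regions — developing eggs, eye, gut,
appendages — that whole-body homogenate lipidomics averages away. This
package implements the complete data path from imzML files to
region-resolved statistics: per-section spectral cleanup, multi-section
study assembly with calibration QC and blank-slide background removal,
declarative region-of-interest annotation, pixel-level multivariate and
univariate statistics, MS1 lipid annotation, and ion-image rendering. A
synthetic whole-body phantom generator with exported ground truth makes
every stage testable at desk scale.

## Data model

A **spectrum** is one pixel's centroided peak list: strictly increasing
m/z values in the 50–1000 Da acquisition window paired with non-negative
intensities. Profile-mode data are rejected by default because every
downstream rule (signal-to-noise filtering, ppm alignment) is
peak-based. A **section** is a pixel grid of spectra (default pixel size
35 µm) plus study metadata — subject, time point (8/24/48/72 h after the
sixth brood), treatment (control or BPA), acquisition order — which
imzML has no standard slot for, and which therefore lives in a sidecar
YAML manifest keyed by section id. imzML coordinates are 1-based with
x = column and y = row; internal image arrays are `[row = y, col = x]`.
A **feature matrix** is pixels × consensus-m/z features with explicit
missingness: a peak absent from a pixel is `NA`, never 0, because
absence below the detection threshold is not a measured zero.

## Per-section preprocessing

The fixed stage order is: SNR filter → 25 ppm alignment → 5% pixel
filter → RMS normalization. Each run records an audit log of per-stage
peak/feature counts.

**Noise and SNR.** The noise level of a pixel is the median absolute
deviation of its peak intensities (`mad_scale` default 1 — plain MAD,
no 1.4826 Gaussian consistency factor, since a bare MAD is the
convention in this workflow; the factor is exposed as a parameter).
Peaks with intensity/noise below `snr_min = 3` (the conventional limit
of detection) are removed. When the MAD is zero (constant or singleton
spectra) the SNR is undefined and all peaks are kept — a degenerate
spectrum must not be annihilated. Whether the inequality is strict is
not fixed by convention; this implementation keeps peaks at exactly
3 × noise.

**Alignment.** Peaks from all pixels are pooled, sorted, and cut into
clusters wherever the gap between consecutive m/z values exceeds
`tol_ppm × (lower m/z) × 1e-6`. This single-linkage gap rule was chosen
because only a tolerance is specified by the workflow it implements: it
is deterministic, order-independent, and provably identical to
brute-force transitive merging (property-tested against an independent
O(n²) oracle). The consensus feature m/z is the intensity-weighted mean
of member peaks — bright peaks are better mass estimates — with a plain
mean available by flag. When one pixel contributes several peaks to a
cluster the most intense is kept, ties broken toward lower m/z.
`align_section(min_pixels =)` can prune clusters below a pixel-support
threshold during alignment; this is exactly equivalent to aligning and
then filtering, but avoids materializing tens of thousands of
single-pixel noise columns as a dense matrix.

**Pixel filter and normalization.** Features observed in fewer than
`ceiling(0.05 × n_pixels)` pixels are removed (the boundary is strict:
"less than 5%"). Each pixel's observed intensities are then divided by
their root mean square, computed over observed values only — zeros are
never imputed before normalization — leaving every pixel with RMS 1.

## Study assembly and calibration QC

Section-level centroids are aligned across the study with the same gap
rule at 35 ppm (looser than the within-section 25 ppm, absorbing
multi-day drift); section order is immaterial (permutation-invariance is
tested). Single linkage matters here: consecutive sections drift by
~2 ppm, far within tolerance, so a lipid's centroids chain into one
study feature even when the first and last sections differ by more.

**Background removal.** Features matched (same gap rule, 35 ppm, since
no separate blank-matching tolerance is specified) to a feature of the
pooled blank slides are removed when the median tissue intensity is
below 10× the median blank intensity. The tissue median treats missing
values as zero by default: a feature absent from most tissue pixels has
a low median and is correctly biased toward removal; the observed-only
alternative is a flag. Both blank slides (acquisition start and end) are
pooled, as the workflow leaves the ordering unstated.

**Calibration.** Rhodamine 6G yields a single intense cation
C28H31N2O3+ at m/z 443.2335 when computed as the plain elemental sum —
the conventional printed value; with electron-mass correction it is
443.2329, and both conventions are exposed. Drift beyond 25 ppm flags
recalibration. Polyalanine [M+H]+ oligomers
(n × 71.03711 + 18.010565 + 1.007276, restricted to 50–1000 Da) provide
calibrants across the whole range; `fit_recalibration` fits the ppm
error as a constant or as linear in m/z and `apply_recalibration`
multiplies every m/z by `1 − predicted_ppm × 1e-6`. The pipeline
recalibrates each section against the rhodamine ion before study
alignment: with a monotone drift of 2 ppm per acquisition index, late
sections sit ~50 ppm off, and without recalibration the 25 ppm
annotation window would be unreachable — which is precisely the role
this QC plays in the acquisition design it models.

## Regions of interest

ROIs are declarative config objects — ellipses
(center, semi-axes, rotation) and polygons — rather than interactive
selections, so the phantom generator can export its geometry in the
same schema and annotation becomes testable against ground truth. Each
ROI carries a unique `id` and a `region` label; several ROIs may share a
region (the six egg discs are all `region = "eggs"`) and act as a
union. Interior tests are boundary-inclusive (ellipse quadratic form
≤ 1; even-odd rule for polygons). A pixel receives the region of the
deepest-nested ROI containing it, children being evaluated only inside
their parent — the two-stage brood-chamber → eggs annotation that makes
egg pixels separable from the bright surrounding tissue. Equal-depth
overlap between different regions is a configuration error, never a
silent tie-break. When a `tissue` ROI is present, pixels outside every
ROI are dropped: background pixels would otherwise dilute the
percentage-based filters (1000 background pixels alongside 1000 tissue
pixels would halve the effective pixel filter).

## Statistics

The statistical path mirrors the three analyses it supports
(tissue types, egg time course, exposure contrast):

1. **Balanced sampling** of 200 pixels per group (seeded, reproducible;
   smaller groups are taken whole with a warning) prevents large
   tissues from dominating the PCA.
2. **50% filters**: a feature must be observed in ≥ 50% of the pixels
   of *at least one* group (per-group, so tissue-specific lipids
   survive), then pixels missing > 50% of the retained features are
   dropped — in that order. The source workflow names "a 50% pixel
   filter and missing value filter" without elaboration; this split is
   the package's reading, and both thresholds are parameters.
3. **95% confidence ellipse**: per group, pixels are imputed, pareto
   scaled and projected on PC1–PC2; pixels whose squared Mahalanobis
   distance under the group's 2×2 score covariance exceeds the
   chi-square quantile with 2 df (5.991 at 0.95) are removed. The
   ellipse is taken on two components, the plane a score-plot ellipse
   is drawn in.
4. **KNN imputation** (k = 5): pixel distances are root-mean-squared
   differences over mutually observed features (the overlap scaling
   makes distances comparable across different overlaps — imputation
   runs before scaling and missingness is structured, so unscaled
   Euclidean sums would favour small overlaps); each missing entry
   becomes the mean of the k nearest pixels observing that feature.
5. **Pareto scaling**: per feature, `(x − mean)/sqrt(sd)`, the
   metabolomics compromise between unit-variance and no scaling;
   constant features become zero columns.
6. **PCA** by SVD with `var_explained = σ²/Σσ²` and a fixed sign
   convention (each loading's largest-|element| positive) so scores
   are bit-reproducible across runs and platforms.
7. **Rank tests with BH-FDR**: the exposure contrast uses the
   Mann–Whitney rank-sum test at pixel level (exact when the smaller
   group has ≤ 8 values and no ties; tie-corrected normal approximation
   otherwise), with Benjamini–Hochberg adjustment across features and a
   direction column (sign of the exposed − control median difference).
   A paired signed-rank mode on per-section medians (n = biological
   replicates) is also exposed: the study this models names a
   signed-rank test but reports FDR p-values of ~10⁻²² that are only
   reachable with pixel-level n, so the pixel-level rank-sum is the
   default for significance, while per-section medians drive the trend
   tables. Degenerate inputs (all values tied, all differences zero)
   give p = 1 with a warning.

## MS1 lipid annotation

Monoisotopic masses are summed from most-abundant-isotope constants
(C, H, N, O, P, S, Na, K); lipid shorthand expands as PC(c:d) →
C(c+8)H(2c−2d+16)NO8P and TG(c:d) → C(c+3)H(2c−2d+2)O6. The four common
positive DESI adducts ([M+H]+, [M+Na]+, [M+K]+, [M+NH4]+) are searched
for every library lipid — which adduct a study assigned to a printed ion
is not recoverable, so the minimum-|ppm| hit within 25 ppm is flagged as
best. Adduct masses carry electron-mass correction (physically correct
for a cation); the calibrant constant deliberately does not, matching
its printed convention, and both flags are exposed. A library may carry
a per-lipid `adduct` column for targeted annotation — used when matching
against the phantom panel, whose emission adducts are known, because
PC(32:0)[M+Na]+ and PC(34:3)[M+H]+ sit only 2.5 ppm apart and a single
5 ppm-jittered peak cannot distinguish them (study *centroids*, which
average the jitter down to ~0.2 ppm, can). Annotations are putative
MS1-only; MS/MS, isotope-pattern and mobility evidence are out of scope.

## Ion images

An ion image sums, per pixel, the intensities of all features within a
ppm window (default 35 ppm, the study alignment tolerance) of a target
m/z. Missing values and dropped off-tissue pixels render as 0,
consistent with detection dropout. `common_scale` sets a series of
images to one global intensity maximum so a given intensity maps to the
same color across a temporal or exposure series; rendering maps
`[0, scale_max]` linearly onto a perceptually uniform colormap (viridis
via `grDevices::hcl.colors`) and writes deterministic PNG bytes.

## The synthetic phantom

`default_phantom_spec()` defines a 50 × 80 grid (4000 pixels/section,
35 µm) holding a body ellipse with eye, gut and appendage regions, and
a brood chamber containing six egg discs. Twenty panel lipids (ten PC,
ten TG, including PC(32:0), PC(34:3), TG(48:5), TG(50:6)) are each
emitted as a single adduct ([M+Na]+ for PC, [M+K]+ for TG) with
pairwise spacing > 100 ppm, so annotation is unambiguous at 25 ppm.

What the generator emulates, and the reasoning behind each choice:

* **Region phenotypes.** Base abundances give each region a distinct
  relative composition: PC accumulates in eggs and eye, TG in
  appendages and eggs, so the PC:TG ratio orders the tissues
  (eye ≫ eggs > body > gut > appendages), sharpened by region-signature
  species. Relative profiles are what matters: after RMS normalization
  absolute intensity is gone, and only compositional contrasts can
  separate tissues in the PCA.
* **Egg development.** Control egg class multipliers across
  8/24/48/72 h are [1, 1, 1.1, 1.8] for PC and [1, 0.85, 0.70, 0.55]
  for TG — PC rises steeply only late, TG declines steadily. No numeric
  effect sizes are reported for the trends this emulates; these values
  are generator conventions chosen once for desk-scale power and are
  config-exposed.
* **BPA at 48 h.** Exposure multiplies egg PC by 0.6 and egg TG by 1.5,
  mirrored at the storage sites (eye for PC, appendages for TG), with
  72 h back at control levels — a perturbation against the
  developmental trend, detectable at ~300 egg pixels per arm.
* **Noise and missingness.** Observed intensity is true intensity times
  lognormal noise (σ_log = 0.3); peaks below the detection threshold
  (40 counts) are dropped, so missingness is mechanistic dropout, not
  MCAR masking. Every pixel also carries a dense forest of chemical
  noise peaks (Poisson(40) per pixel, median 55 counts, uniform m/z):
  this forest is what makes the MAD a *noise* estimate rather than a
  signal-spread estimate, and it is exactly the population the SNR and
  pixel-frequency filters exist to remove. Without it, a 27-peak pixel
  would have MAD on the order of the signal spread and the SNR filter
  would eat genuine low-abundance peaks.
* **Mass accuracy.** Per-peak m/z jitter is Gaussian (σ = 5 ppm) on top
  of a monotone drift of 2 ppm per acquisition index; blank slides sit
  at indices 0 and 25. Seven intense background ions (including the
  rhodamine 6G calibrant, present on every slide by design) appear in
  all pixels of all slides at comparable magnitudes (650–1500 counts),
  so none falls under a blank pixel's own SNR threshold.
* **Acquisition design.** 24 sections in 12 blocks of two, each block
  holding both treatments of one (time, replicate) cell, block and
  within-block order shuffled — treatment is balanced against the
  drift.

What it does **not** emulate: peak shapes and centroiding artifacts,
spatial intensity gradients within a region, ion suppression between
co-located lipids, isotope envelopes, chimeric peaks, or vendor-writer
imzML dialects. Passing recovery tests therefore show that the
*processing logic* is correct under a faithful statistical structure,
not that the pipeline is robust to every artifact of real instruments.

## Numerical and design choices

* Tolerances: alignment 25/35 ppm and annotation 25 ppm are workflow
  constants; round-trip m/z fidelity is ≤ 1e-6 Da (64-bit storage) and
  intensity ≤ 1e-4 relative (32-bit storage).
* Pixel-filter threshold is `ceiling`-based with a strict boundary;
  conf → 1 makes the ellipse filter a no-op; `min_frac = 0` makes the
  pixel filter a no-op.
* Degenerate inputs are defined, not crashed: zero-MAD spectra keep all
  peaks; singular group covariance skips the group with a warning;
  all-tied rank tests return p = 1; pixels left featureless after
  filtering are dropped before RMS normalization with their identity
  reported.
* All stochastic steps (sampling, simulation, blocking) flow from
  explicit seeds; per-section seeds derive from the root seed, and
  imzML identifiers are content-derived so identical simulations give
  identical files.
* Problem sizes: the packaged study is 26 imzML files of 4000 pixels
  each (~1700 tissue pixels/section); the test suite's oracle checks
  run at ≤ 200 peaks × 1000 instances, enumeration tests at ≤ 6 values
  per group, and the ellipse calibration at 10,000 pixels. These sizes
  exercise every code path while keeping a full run on one CPU within
  minutes.

## Known limitations

* The imzML reader is tested against this package's writer, small
  hand-built fixtures and the pyimzML parser; vendor-converter dialect
  quirks are untested.
* MS1 annotation is putative by construction; near-isobaric
  (lipid, adduct) pairs inside 25 ppm are reported ranked by |ppm|, and
  the best hit can be wrong for single noisy peaks (see the
  annotation section).
* The pixel-level rank-sum test treats pixels as exchangeable units
  within a group; pixels within one section are spatially correlated,
  so its p-values overstate independent evidence — the per-section
  median path is the conservative alternative.
* Anomalous-pixel removal is purely the quantitative 95%-ellipse rule;
  no by-eye curation step is modelled.
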