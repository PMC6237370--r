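---
title: "Per-lesion CT radiomics for response prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-lesion CT radiomics for response prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Liver metastases of esophagogastric cancer respond to chemotherapy very
unevenly: within one patient some lesions can disappear while others grow.
Clinical response criteria (RECIST) summarize a patient by a few target
lesions and cannot anticipate which individual lesions will respond.
`lesionrad` implements a per-lesion analysis of this question: quantify each
lesion's pre-treatment CT phenotype as a radiomics feature vector, define
each lesion's observed response from its volume change between the
pre-treatment and evaluation scan, and ask how well a random forest trained
on other patients' lesions predicts that response.

The pipeline has four stages, each usable on its own:

1. **Cohort I/O** (`load_manifest()`, `read_volume()`, `resample_to_grid()`):
   NIfTI volumes and per-lesion 3D masks, linked by a CSV manifest, are
   resampled to a common analysis grid of 1 x 1 x 2 mm voxels with trilinear
   interpolation.
2. **Feature extraction** (`extract_features()`): a 370-entry feature vector
   per lesion — 7 first-order intensity statistics, 19 shape descriptors,
   65 texture features from six grey-level matrix families on the original
   image, and 279 statistics/texture features on the eight sub-bands of a 3D
   stationary wavelet transform.
3. **Response labeling** (`label_responses()`): per-lesion percent volume
   change; a lesion is a *responding lesion* (PR) when its volume decreases
   by strictly more than 65%, and a *complete response* (CR) when it is no
   longer detectable at evaluation. The 65% cut-off is the volume equivalent
   of the RECIST 30% diameter decrease: `100 * (1 - (1 - 0.30)^3) = 65.7`,
   floored to 65 (`recist_equivalent_volume_threshold()`).
4. **Modeling** (`fit_lopo()`): random forests (150 trees, terminal node
   size 1) under leave-one-patient-out cross-validation; out-of-fold scores
   of all lesions are pooled into one validation ROC with a DeLong 95%
   confidence interval; per-fold Gini importances are averaged and audited
   against baseline lesion volume with Pearson correlations (significance at
   p < 0.0001).

# Feature definitions and numerical choices

**Discretization.** All texture families operate on grey levels obtained by
equal-width binning of in-mask intensities into 32 bins spanning the ROI's
own min-max range, independently per image channel. ROI-relative binning
makes every texture feature invariant to global intensity shifts (tested as
an invariant) and is the common choice for relative-intensity CT texture. A
constant ROI maps to a single level. The bin count is a parameter of
`discretize()` and of the catalog.

**Texture matrices.** GLCM and GLRLM are computed per direction over the 13
unique 3D offsets at distance 1 voxel, features derived per direction and
averaged — the standard isotropy-restoring aggregation. GLSZM/GLDZM zones
are 26-connected components of constant grey level; GLDZM zone distance is
the Chebyshev distance to the nearest out-of-mask voxel (grid edge counts as
outside, minimum 1). NGLDM uses the 26-neighbourhood with dependence
tolerance 0; NGTDM uses the mean over in-mask 26-neighbours. Offsets are
defined in voxel units, not millimetres: on the anisotropic 1 x 1 x 2 mm
grid a z-step spans twice the in-plane distance, matching common practice
for in-plane-dominant CT texture and documented here as a limitation.

**Degenerate ROIs.** A constant or tiny (1-2 voxel) ROI has no texture. So
that the downstream forest always receives finite inputs: correlation-type
GLCM features fall back to 1, entropy-type features to 0, and NGTDM
coarseness is `1 / (sum(p * s) + 1e-6)`, capping it at 1e6. The extractor
asserts that no NaN/Inf ever escapes.

**Wavelet channel.** A single-level undecimated (stationary) separable 3D
wavelet transform with the `coif1` filter pair and half-sample symmetric
boundary extension, computed on the lesion bounding box padded by the filter
length. Undecimated filtering keeps all eight sub-bands (LLL ... HHH, filter
order x, y, z) on the input grid, so the original lesion mask applies to
every band without resampling. High-pass bands of a constant volume are
exactly zero, and impulse responses equal the separable filter tensor
products (both tested). `haar` and `db2` are available as options.

**Shape.** Volume is voxel count times voxel volume. Surface area is a
marching-cubes triangulation: the binary mask is padded, lightly smoothed
(Gaussian, sd 0.75 voxel), and the 0.5 level set is triangulated with
linearly interpolated edge crossings; a frozen per-pattern topology table
drives the triangulation. Raw voxel-face counting overestimates a smooth
surface by up to 50% (staircase bias), which would push sphericity of a
sphere to ~0.65; the triangulated estimate is nearly unbiased. Sphericity,
compactness and spherical disproportion pair the mesh area with the mesh's
own enclosed volume (divergence theorem over the same triangles), so
sphericity provably respects the isoperimetric bound of 1. Maximum 3D and
per-plane 2D diameters are largest pairwise distances between boundary
voxel centres, with deterministic subsampling to 1500 boundary points for
very large lesions (error at most about a voxel at cohort scales).
Principal axis lengths, elongation and flatness come from the second
spatial moments. The catalog's 19 shape entries contain no placeholder
features: every entry carries geometric information.

**The catalog.** The exact composition of the 65 original-image texture
features and the 279 wavelet-channel entries is configuration, not code:
`inst/extdata/default_catalog.yaml` lists all 370 entries in order (GLCM 18,
GLRLM 11, GLSZM 11, GLDZM 11, NGLDM 9, NGTDM 5 on the original image; per
wavelet band 7 statistics plus 28 texture features, minus one entry in the
LLL band so the wavelet block totals 279). Alternative catalogs load with
`read_catalog()`.

# Modeling choices

- **Training AUC** per fold is computed from out-of-bag votes: the
  resubstitution AUC of a node-size-1 forest is essentially 1 and carries no
  information. Resubstitution is available as an option.
- **Scores** are the fraction of trees voting positive; tie-rich score
  distributions are handled by the midrank (half-tie) AUC, which is tested
  to match brute-force pair counting exactly.
- **Confidence intervals** for the pooled validation AUC use DeLong's
  nonparametric estimator by default; a seeded 2000-resample bootstrap is
  the alternative.
- **No feature scaling or selection** precedes the forest: forests are
  invariant to monotone feature transforms, and the feature set is fixed by
  the catalog.
- **Seeds.** One master seed; per-fold forest seeds are derived
  deterministically from it, so a whole leave-one-patient-out run is
  bit-reproducible (tested).
- **Degenerate folds** (a training set with one class) produce flagged
  constant scores rather than failures.
- The strict reading of "more than 65%" makes a lesion at exactly -65.000%
  a non-responder; the boundary case is tested.

# The synthetic cohort generator

No imaging data ships with the package, so `generate_cohort()` creates
paired-timepoint cohorts with known ground truth. Defaults emulate the
target study's geometry: 18 patients; lognormal lesion counts with median
10, clamped to 1-42; baseline volumes log-uniform over 0.06-195 mL (the
three-decade range such cohorts show); P(PR) = 0.51 and P(CR | PR) = 0.47.
Lesions are ellipsoids with randomized axis ratios and a smooth multiplicative
surface perturbation; in-mask intensity is a 60 HU base plus a Gaussian
random field (texture) plus 5 HU white noise, over a 30 HU background.

The class signal lives in spatial autocorrelation, mirroring the
observation that most predictive CT features measure tumour heterogeneity:
responders get texture correlation length `4 * exp(-delta/2)` mm and
non-responders `4 * exp(+delta/2)` mm. At `delta = 0` the classes are
exactly exchangeable at baseline — the null-calibration condition. The
default `delta = 2 * log(2)` gives 2 mm vs 8 mm, the signal-recovery
condition. A separate switch (`size_coupled_cr`) couples the probability of
complete response to lesion volume (`v^-1.5`, rescaled so the marginal CR
rate is preserved), emulating the finding that disappearing lesions are
significantly smaller at baseline; it is off by default and on in the
size-scenario evaluations, where it makes the CR task easier than the PR
task by construction.

Evaluation-timepoint masks are re-rendered from the same per-lesion seed
with radii scaled by `(1 + pct/100)^(1/3)`; CR lesions are simply absent
from the evaluation manifest. Every lesion carries its own rendering seed in
the truth table, so `regenerate_from_truth()` reproduces byte-identical
files.

What the generator does **not** emulate: whole-liver/abdominal anatomy,
partial-volume and beam-hardening physics, scanner- and protocol-dependent
texture, inter-observer delineation variability, and registration error
between timepoints. Passing tests therefore demonstrate that the pipeline
recovers the kind of signal it models (autocorrelation differences, size
effects) under controlled conditions — not that such signal is recoverable
from real scanners at these effect sizes.

# Problem sizes used by the test suite

The heavier properties run on reduced cohorts chosen as the package's own
test conditions: null calibration uses 20 cohorts of 8 patients with 3-6
lesions each (0.2-2.5 mL, 64-voxel grids); signal recovery uses 2 cohorts of
8 patients (up to 6 lesions, 0.3-6 mL); the size-coupled scenario uses 3
cohorts of 10 patients with 4-8 lesions (0.2-8 mL). Oracle-equivalence
checks run all six texture builders against brute-force enumeration on 100
random 4x4x4 ROIs.

# Known limitations

- **Pooled grouped cross-validation is pessimistic at small cohort sizes.**
  Pooling out-of-fold scores across leave-one-patient-out folds mixes models
  trained on different class priors: holding out a positive-heavy patient
  depletes the training prior, which lowers that fold's scores while its
  held-out labels are enriched for positives. Under a true null this
  anti-correlation pushes the pooled AUC *below* 0.5, and the bias grows as
  the held-out fraction per fold grows. At the study's own scale (18
  patients, about 200 lesions) the effect is small; on 8-patient reduced
  cohorts it is clearly visible, and the null-calibration acceptance check
  measures it directly. Per-fold training AUCs (out-of-bag) do not share
  this artifact.
- Texture offsets are voxel-based on an anisotropic grid (see above).
- The marching-cubes surface slightly smooths away curvature below about a
  voxel, so surface areas of very small lesions (under roughly 0.1 mL) are
  underestimated; volume features are unaffected.
- Maximum-diameter features subsample very large boundaries (deterministic,
  documented above).
- The generator draws lesion volumes log-uniform rather than fitting a
  parametric size distribution; only the range and median structure of the
  target cohort are matched.
- Scan-quality screening by acquisition metadata (kVp, slice thickness,
  contrast phase) is out of scope: synthetic volumes carry no DICOM headers.
  Manifests may carry extra QA columns, which are preserved but not acted on.
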