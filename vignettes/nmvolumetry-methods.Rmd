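---
title: "Neuromelanin-sensitive MRI volumetry: model, phantom, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuromelanin-sensitive MRI volumetry: model, phantom, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Neuromelanin-sensitive MRI (NM-MRI) visualizes the melanized neurons of the
substantia nigra pars compacta (SNc) and the locus coeruleus (LC) as
hyperintense regions in magnetization-transfer-weighted images. Both nuclei
lose pigmented neurons in Parkinson's disease (PD), so their apparent
volumes are candidate imaging markers of neurodegeneration. The LC is a
particularly hard target: a bilateral rod roughly 2 mm across and 15 mm
long, imaged here on a 0.39 x 0.39 mm in-plane grid with 3 mm slices.

`nmvolumetry` implements the full measurement chain as a reusable,
testable pipeline:

1. **Motion correction and averaging.** Seven repeated measurements are
   rigidly registered to the first and averaged voxelwise.
2. **Reference statistics.** A cerebral-peduncle reference ROI, defined in
   standard space and mapped to the native grid through a precomputed
   transform chain composed into a single map (one interpolation pass),
   yields the reference mean and SD, mu_ref and sigma_ref (sample SD,
   n - 1 denominator).
3. **Search regions.** Standard-space probabilistic SNc/LC atlases are
   mapped to native space, thresholded at 5% probability, and binary-dilated
   (6-connected, 2 iterations by default) so the whole structure is
   inside the search region.
4. **Threshold segmentation.** Voxels of the search region with intensity
   strictly greater than mu_ref + k sigma_ref belong to the structure:
   k = 2.8 for SNc and k = 3.9 for LC (the higher LC cut compensates for
   susceptibility effects near the fourth ventricle). Left and right
   hemispheres are summed into one bilateral volume, voxel count times
   voxel volume (0.456 mm^3 at the acquisition grid).
5. **Cohort statistics.** Shapiro-Wilk normality checks, two-tailed Welch
   t-tests, ANCOVA with age and education covariates, age-adjusted Pearson
   (partial) correlations with clinical scores, and ROC analysis — empirical
   AUC with Hanley-McNeil standard errors (DeLong optional), plus a combined
   SNc+LC marker from a binary logistic model.

No clinical images ship with the package; a parametric phantom generator
with exact ground truth stands in for scanner data, which is what makes the
whole chain verifiable.

## The phantom generator

`phantom_spec()` / `generate_subject()` emulate the acquisition:

* **Geometry.** A 64 x 64 x 14 grid of 0.39 x 0.39 x 3 mm voxels. SNc is a
  bilateral crescent band (outer disc of radius 6 mm minus an offset
  cutting disc) spanning three superior slices; LC is a bilateral rod pair,
  nominally 2 mm x 15 mm, scaled isotropically so its voxelization matches
  the requested true volume; the reference region is a pair of lateral
  boxes in the SNc slice band. Structures are voxelized by ranking voxels
  on a signed inside-ness score and taking exactly
  `round(volume / voxel_volume)` of them, so ground-truth masks hit any
  requested volume to within half a voxel.
* **Scene sampling.** The scene is painted blockily on a 2x supersampled
  grid, and every measurement — including the first — is produced by
  sampling that scene onto the acquisition grid under its rigid pose
  (identity for measurement 1, independent jitter of SD 0.5 degrees /
  0.5 mm per axis for the rest). All measurements therefore undergo
  identical partial-volume smoothing, as in a real scanner; a simulator
  that interpolates only the moved measurements would hand the registration
  stage a systematically sharper reference image, which real data never
  does. With noise, blur and motion off, measurement 1 equals the blocky
  scene exactly, which is what makes exact-recovery tests possible.
* **Intensity model.** Background at 100 intensity units; both structures
  at +30 (SNc, 6 measurement-SDs) and +50 (LC, 10 measurement-SDs — the LC shows the strongest neuromelanin contrast in vivo and its thin rod pays the largest partial-volume toll); i.i.d. Gaussian receiver noise of SD 5 per
  measurement (Rician optional — magnitude MRI noise is Rician at low SNR,
  nearly Gaussian at this contrast); an optional 0.25 mm FWHM acquisition
  blur (k-space apodization scale); and a *fixed* smooth
  tissue-heterogeneity field of SD 4.5 (correlation ~1.2 mm in-plane, ~2
  slices through-plane). The tissue field is the phantom's key realism
  ingredient: it is present in the reference region and the search regions
  alike and does not average away over the 7 measurements, so sigma_ref on
  the averaged image is dominated by tissue variance — as in acquired
  NM-MRI — and the reference ROI genuinely represents the search-region
  background, which is the homogeneity assumption of the thresholding
  method. It also gives the rigid registration a fixed pattern to lock
  onto.
* **CNR choice.** No per-structure contrast-to-noise figures accompany the
  printed cohort summaries this package is calibrated against, so contrast
  is a phantom parameter, not a reproduction target. The default (contrast 30 and 50, tissue SD 4.5, noise SD 5)
  puts the thresholds mu_ref + 2.8 sigma_ref and mu_ref + 3.9 sigma_ref at
  roughly half to two-thirds of the structure contrast on the averaged
  image: high enough that supra-threshold background is rare, low enough
  that the thresholds do real work. Passing phantom tests shows the chain
  is correct under these conditions; it does not certify performance at
  arbitrarily low CNR, on real susceptibility artifacts, or under
  non-rigid motion.
* **Atlases.** Published SNc/LC atlases are external resources; the phantom
  ships its own standard-space atlas pair — the ground-truth masks smoothed
  (2 mm in-plane, one-slice leak through-plane) and peak-normalized — plus
  the reference ROI, so the pipeline runs with no downloads. For phantoms,
  standard space coincides with native space and the ground-truth chain is
  the identity; for real data the chain would come from an external
  registration tool, which this package deliberately does not reimplement.

## Cohorts

`cohort_spec()` draws per-subject true volumes from group-specific normal
distributions truncated below at 5% of the group mean (the PD LC mean sits
only ~1.4 SD above zero, so untruncated sampling can go nonphysical).
Defaults reproduce the validation-cohort summary statistics: 33 controls
vs 39 PD; SNc 429 vs 329 mm^3, LC 8.0 vs 5.2 mm^3; per-subject SDs are
recovered from the printed standard errors as SE x sqrt(n) (SNc
114.9/106.2 mm^3, LC 3.45/3.75 mm^3). Demographics and clinical scores
(age, sex, education, UPDRS-III, MoCA, NMSQ, RBD-SQ, disease duration,
levodopa-equivalent dose) are drawn from the same summary table's means
and SEs-times-sqrt(n), rounded to plausible scales. These are marginal
draws: the generator does not model correlations between clinical scores
and volumes, so cohort-level correlation analyses on synthetic data test
machinery, not biology.

## Numerical and design choices

* **Coordinates.** 0-based voxel indices map to RAS world mm through the
  NIfTI affine; all resampling composes the full transform chain into one
  4x4 and interpolates once (trilinear for intensities and probabilities,
  nearest-neighbour for masks; out-of-field voxels fill with 0).
* **Registration.** 6-DOF rigid, mean-squared-error cost on a stride-2
  in-plane subsample of the grid interior (an 8-voxel in-plane / 1-slice
  margin is excluded so border voxels swept out of field do not bias the
  fit), rotation parameterized about the image center. Both images are
  pre-smoothed identically (Gaussian, sigma 1.0 voxels in-plane, 0.7
  slices through-plane) before the cost is evaluated: trilinear resampling
  smooths the moving image by an amount that depends on the fractional
  offset, which tilts an unsmoothed MSE toward integer-voxel poses, and
  pre-smoothing damps that tilt along with the noise. Optimization is a
  fixed 27-point translation multi-start, two Nelder-Mead passes, then a
  cyclic per-parameter parabolic polish at 0.05 and 0.01 (degrees/mm)
  steps — deterministic by construction, no randomness anywhere.
  Registration accuracy is quoted as RMS voxel displacement: map every
  voxel center through estimated and true transforms and take the RMS of
  the per-axis discrepancies divided by that axis's voxel dimension,
  evaluated over the imaged anatomy (structure + reference voxels), the
  region whose alignment the measurement needs. A point worth stating
  plainly: at the default tissue CNR of 0.9 the estimator operates at the
  information limit of a measurement pair — its error (~0.1 voxel RMS,
  i.e. ~0.04 mm in-plane) is set by how much pose information the noise
  leaves in the images, not by the optimizer; denser cost sampling,
  symmetric half-transform costs, and re-registration to the running
  average were all measured to give no improvement. Sub-0.1-voxel recovery
  claims are therefore validated on a high-texture registration phantom
  (`tissue_sd = 9`, CNR 1.8), while the default-CNR figure is reported as
  its own quantity. For the same reason the sqrt(7) noise-reduction
  property of averaging is checked against plain i.i.d. averaging of a
  motion-free series: motion correction's sub-voxel resampling offsets
  additionally smooth the noise and overshoot sqrt(7) by design.
* **Thresholding.** Strict ">" at mu_ref + k sigma_ref; ties excluded. No
  connected-component filtering or minimum cluster size is applied (the
  method defines none); a component count can be reported for information.
* **Welch from summaries.** t = (m_a - m_b)/sqrt(se_a^2 + se_b^2) with
  Welch-Satterthwaite df; printed group summaries are valid inputs, which
  is how the package reproduces the published worked example.
* **ROC orientation.** Volumes shrink with disease, so scores are negated
  internally (recorded in the result) and AUC > 0.5 corresponds to
  PD-lower-than-control. AUC standard errors default to Hanley-McNeil
  (the historical SPSS convention); DeLong is available.
* **Marker combination.** The source analysis does not say how SNc and LC
  volumes were combined; binary logistic regression on both volumes, with
  the fitted disease probability as the combined score, is the standard
  choice and is recorded in the output. Under perfect separation the MLE
  diverges; a lightly ridge-penalized fit (lambda = 1e-4 on standardized
  predictors) is used with a warning.
* **Multiple testing.** None is applied (matching the source analysis,
  single alpha = 0.05); every test performed is logged in the report so
  the count is visible.
* **Correlations.** Age is the covariate in all volume-clinical
  correlations; education is not additionally partialled out (the source
  states age only).

## Problem sizes used in validation

The test-suite and acceptance problem sizes are chosen to give stable
statistics at interactive runtimes: 1000 random 16 x 16 x 8 images for the
segmentation brute-force oracle; one default phantom subject (7
measurements, 64 x 64 x 14) for end-to-end recovery and registration
checks; 2000 volumes-only replicate cohorts for type-I error; 200
replicates at the study's 33/39 group sizes for effect detection; 25
replicate cohorts for ROC summaries. Empirical rates at these sizes have
binomial SEs of about 0.005 (type-I) and 1.5% (power), comfortably inside
the acceptance margins.

## Known limitations

* Contrast is parametric; no pulse-sequence physics (T1/T2*/MT) is
  simulated, so protocol questions (flip angle, MT pulse design) are out
  of reach.
* Only rigid motion between measurements; no within-measurement artifacts,
  no susceptibility dropout near the fourth ventricle — the very effect
  that motivates the higher LC threshold is not in the phantom.
* Nonlinear standard-to-native registration is consumed (as precomputed
  chains), never estimated; brain extraction is out of scope.
* The phantom's crescent/rod geometry is schematic. Its atlases derive
  from the same geometry, so atlas-placement error on real anatomy is not
  represented.
* Volume ground truth is defined before blur and partial-volume effects;
  segmented volumes on the default phantom carry a few-percent positive
  bias from edge partial volume, which is physical, not a bug. The effect
  is largest for the LC: with inter-measurement motion, the jittered
  acquisitions plus motion-correction resampling smear roughly a fifth of
  the rod's contrast into its one-voxel shell, and since the whole
  structure is ~18 voxels, the measured LC volume can exceed truth by
  several voxels (tens of percent on single subjects). The acceptance
  output reports recovery both without and with motion so this bias is
  visible rather than averaged away.
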