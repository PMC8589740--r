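---
title: "Computational MTA, GCA and Fazekas grading from head CT: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational MTA, GCA and Fazekas grading from head CT: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiologists grade structural brain changes on ordinal visual scales:
medial temporal lobe atrophy (MTA, Scheltens scale, 0–4 per hemisphere),
global cortical atrophy (GCA, Pasquier scale, 0–3) and white-matter-lesion
burden (Fazekas scale, 0–3). These gradings are usually made on MRI, but
many patients only have a head CT. `ctquant` implements an automated
pipeline that estimates all three grades from a CT volume, and the
agreement battery used to compare two grade sources.

The pipeline has five stages:

1. **Skull stripping** by a two-class expectation–maximization (EM)
   intensity model: nonlocal-means denoising, outlier clipping, EM with
   fixed priors over head voxels, a bone threshold derived from the EM
   fit, and morphological fine-tuning into a single hole-free brain mask.
2. **Registration**: a 9-parameter affine (3 translations, 3 rotations,
   3 scales) fitted on the binary skull masks by minimizing the
   sum-of-squared differences of their Gaussian-smoothed indicators;
   optionally refined by a nonrigid displacement field maximizing
   normalized mutual information (NMI) of the grayscale images. The
   nonrigid field refines the transport of template data to native space
   only; the segmentation itself runs in affinely aligned template space.
3. **Segmentation** of CSF and white-matter lesions (WML) with a small
   U-shaped residual convolutional network on the z-scored template-space
   CT, repeated K times with independently seeded trainings and fused by
   the correlation-weighted combination rule: pairwise Pearson
   correlations `c_ij` between member probability maps, per-member counts
   `n_i = #{j : c_ij > min(0.8, 0.9 max_{j != i} c_ij)}` (the self pair
   counts), weights `w_i = n_i / sum n_i`, and a 0.5 threshold on the
   weighted mean probability.
4. **Measures** in native space: MTA-left/right as CSF volume inside the
   per-hemisphere medial-temporal-lobe masks, GCA as the volume where the
   un-thresholded CSF probability exceeds the normative 99th-percentile
   map (globally and per lobe), Fazekas as WML volume inside the deep
   white-matter mask — all normalized by the total brain volume from the
   skull-stripped image.
5. **Calibration**: per scale, ordinary least squares of grade on measure
   followed by a piecewise-linear correction with one knot per observed
   rounded grade, mapping the median step-1 estimate of each grade group
   to the group's median ground-truth grade. Continuous grades are cut to
   the allowed range and rounded to the nearest integer for categorical
   reporting; grades above 1 are flagged "abnormal".

## The synthetic cohort

No clinical cohort ships with the package; a parametric head phantom
(`make_phantom()`) provides paired CT-like volumes, ground-truth tissue
labels and known severities. The phantom is built from nested ellipsoids:
skull shell (with three asymmetric bony landmarks — frontal sinus,
occipital protuberance, right mastoid — so that rigid pose is
identifiable from the skull alone), cortical grey-matter band,
white-matter core, lateral-ventricle analogues, bilateral
medial-temporal CSF pockets whose volume grows linearly with
`mta_severity`, a sulcal CSF rim whose thickness grows with
`gca_severity`, and periventricular lesion blobs whose total volume grows
linearly with `fazekas_severity` (4000 mm³ per Fazekas unit, placed at
seeded random sites around the ventricles). Intensities are
pseudo-Hounsfield constants per class (air −1000, skull 900, GM 38, WM
30, WML 20, CSF 8) plus additive Gaussian noise, default SD 5 HU — a
typical brain-window noise level. Severity-to-volume mappings are linear
by construction so that calibration recovery is well-posed.

What the phantom does **not** emulate: partial-volume mixing beyond the
voxelized class boundaries, beam hardening, scanner-dependent noise
texture, gyral/sulcal anatomy, or anatomical covariance between atrophy
patterns. Passing the synthetic acceptance battery therefore demonstrates
the internal consistency of the pipeline (each stage recovers what the
generator put in), not clinical accuracy.

## Parameters that matter

| Parameter | Default | Rationale |
|---|---|---|
| NLM patch / search radius, strength `h` | 1 / 3 voxels, noise-tied | Patch-based averaging preserves class edges; `h` is 1.5× a median-absolute-difference noise estimate. |
| Outlier percentiles | [0.1, 99.9] | Clip isolated extreme voxels without touching the intensity structure. |
| EM priors | 0.5 / 0.5, fixed | Held fixed during EM; only means/SDs update. |
| Bone threshold | equal-posterior crossing | Root of the two-Gaussian posterior equality between the class means; falls back to 200 HU when classes coincide. |
| Morphology | ball r = 2, open → largest component → close → fill | Single connected, hole-free brain mask. |
| Affine schedule | levels 3×/1.5×/1×, NM multi-start ±7° then BFGS | The SSD of thin skull shells has rotation local minima; the coarse derivative-free multi-start proposes basins and carries the best two to the next level. Masks are smoothed (σ = 1 voxel) so the SSD is differentiable. |
| NMI bins | 32, linear Parzen | Joint histogram smooth enough for a usable ascent direction at 64³. |
| Nonrigid model | first-order B-spline control grid, 8-voxel knots, bending penalty 0.05 | Backtracking gradient ascent; NMI nondecreasing by construction. Off by default in the desk pipeline, where phantom pose is rigid and affine transport is already exact up to voxel sampling. |
| Network (desk) | 4 base channels, 1 down/up stage, 4 residual elements, ~10k parameters | Trains in minutes on one CPU at 64³; the "full" preset matches the uResNet-family architecture scale (3 deconvolutional stages, 8 residual elements, ~10⁶ parameters). |
| Training | Adam 1e-2, warmup 10%, step decay, gradient clipping at norm 1, leaky rectifier (slope 0.05) | Stabilizers against seed-dependent collapse of a very small network; see "Numerical choices". |
| Loss | cross-entropy (class weights count^−0.3) + soft Dice (weight 2) on CSF/WML | The Dice term optimizes thresholded overlap directly, which the voxel-count-dominated CE cannot do for classes at ~10⁻³ prevalence. |
| Ensemble K | 10 by contract; 3 (pipeline default) at desk scale | Independently seeded trainings supply the repetition variability. |
| GCA percentile | 99 | Voxels above the normative 99th percentile of reference CSF probability count as abnormal CSF. |
| `min_abnormal_prob` | 0.05 | Floor on the percentile map: deep white matter has no reference CSF, so the map is exactly zero there and any positive segmentation probability would count as abnormal without the floor. |

## Numerical choices

* **Class weighting and the 0.5 threshold.** Plain inverse-frequency
  weights make the rare lesion class dominate the loss (the phantom's
  class imbalance is roughly 10³:1) and flood the 0.5-thresholded
  prediction with false positives; unweighted cross-entropy never learns
  the class. The package uses mildly tempered weights (`count^-0.3`)
  with a Dice-dominated loss, which places the 0.5 decision boundary
  correctly without posterior tricks. `predict_segmenter(unbias = TRUE)`
  optionally divides the softmax output by the training weights
  (removing the weight tilt of a converged weighted posterior); it is
  off by default because an undertrained network under-shoots its
  confidence and the correction then over-suppresses rare classes.
* **Fusion threshold rule.** In `min(0.8, 0.9 max c_ij)` the maximum is
  taken over the other members; including the self-correlation would pin
  the maximum at 1 and make the 0.9-scaling clause vacuous. The self pair
  does count towards `n_i` (it always passes). Members with zero variance
  have undefined correlations and are excluded with weight 0 and a
  warning.
* **Rounding ties** (e.g. 2.5) round half away from zero; categorization
  clamps to the scale range before rounding.
* **Piecewise calibration**: knots are sorted by estimate; non-monotone
  median targets are repaired isotonically with a warning; beyond the end
  knots the map extrapolates linearly with the end segments' slopes.
* **Network input** is four channels, all fixed functions of the
  z-scored CT: the z map; a tissue-anchored intensity (a two-class EM
  over the brain values locates the CSF and parenchyma means and maps
  parenchyma → 0, CSF → −1 — plain z statistics shift with the CSF
  fraction, i.e. with atrophy severity, which otherwise drags the lesion
  intensity across any fixed decision boundary); the anchored map's
  local contrast (minus its σ = 1.5 voxel blur), a blob feature that
  1–2 voxel lesions need at this network scale; and CSF adjacency (a
  σ = 2.5 voxel blur of anchored < −0.75), which separates
  partial-volume rings hugging large CSF bodies from isolated lesions of
  overlapping intensity. None of the channels adds external
  information.
* **Training supervision in template space** takes the argmax of
  linearly resampled one-hot label maps and ignores (weight 0) voxels
  whose winning class probability falls below 0.7 (0.5 in the pipeline):
  at thin structures, nearest-neighbour labels disagree with the
  trilinearly blended intensities, and training on those voxels teaches
  the network the wrong intensity model.
* **Resampling into template space** uses Catmull-Rom cubic
  interpolation for the CT intensities (trilinear washes out one- and
  two-voxel lesions), trilinear for probability maps and
  nearest-neighbour for masks and labels.
* **Z-scoring for the CNN** computes its statistics on the brain mask
  eroded by 2 voxels: after resampling, mask-boundary voxels blend in
  bone intensity, and even a fraction of a percent of such voxels
  inflates the SD enough to crush the CSF/parenchyma contrast. The
  denoised CT (stage-1 output) feeds the z-scoring, since the phantom's
  10 HU lesion contrast is at the noise level of the raw image.
* **Degenerate inputs** fail loudly: air-only volumes (no head tissue),
  constant images (EM, NMI and z-scoring undefined), empty masks,
  single-voxel masks, missing calibrations, out-of-range grades.
* **Nearest-site lobe extension** measures distance in world mm (robust
  to anisotropic spacing); exact ties resolve to the smaller label code
  (frontal < temporal < parietal < occipital).
* **Percentile maps** interpolate linearly between order statistics
  (type-7), and are permutation-invariant in subject order.

## Problem sizes

The shipped tests and the acceptance script run at the package's desk
scale: 64³ voxels at 2.5 mm, 30-subject training cohorts, 20-subject
held-out cohorts, 2-member ensembles trained for 40 epochs, 20-phantom
skull-stripping sweeps, 12–50-pose registration recoveries and
200-subject calibration sets. These sizes were chosen so a full run
completes on one CPU in well under an hour while every stage still has
enough signal to demonstrate recovery; they are package defaults, and all
of them scale up through the corresponding configuration objects
(`segmenter_config(preset = "full")`, `pipeline_config(K = 10)`, larger
`make_cohort()` calls).

## Known limitations

* The phantom's geometric simplicity means segmentation quality on it
  says little about real CT; on clinical data the pipeline's value rests
  on the evaluation design it implements (reference-graded cohorts and
  the agreement battery), not on these synthetic numbers.
* The desk-scale network is deliberately tiny; its lesion segmentation is
  the weakest stage, and the Fazekas measure inherits that noise. At the
  2.5 mm desk grid lesions span only one to two voxel radii and lose
  about half their 10 HU contrast in the resampling to template space, so
  the per-subject lesion detection level varies enough to degrade the
  continuous Fazekas correlation even when the categorical
  (within-one-grade) agreement holds — mirroring the clinically reported
  difficulty of grading minor lesion burdens on CT. Finer voxels or the
  "full" network preset address this at correspondingly higher compute.
* The affine stage assumes the skull is rigid and visible; post-surgical
  or pediatric anatomy is out of scope.
* Left/right MTA are calibrated per hemisphere; the combined MTA grade is
  reported as the mean of the two continuous grades before
  categorization.
* Per-lobe GCA uses lobe-specific calibration models fitted against the
  same global severity, since the generator has a single global atrophy
  parameter.
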