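---
title: "Automated delineation of stroke lesions from brain CT: models and methods"
author: "ctlesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated delineation of stroke lesions from brain CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Non-contrast CT is the workhorse imaging modality of the acute stroke unit.
On CT, a hemorrhage appears hyper-intense (bright) and an ischemic infarct
hypo-intense (dark) relative to normal parenchyma. Manual slice-by-slice
tracing of those regions is slow and operator-dependent, which limits the
construction of large lesion databases for lesion-symptom mapping.

`ctlesion` implements a fully automated alternative: normalize each patient
CT into a common (template) space, compare it voxel-by-voxel against a
normative model built from lesion-free control CTs, and threshold the
resulting statistic map into a ternary lesion map (-1 = ischemia, 0 =
normal, +1 = hemorrhage), which can be carried back to the native scan by
inverting the spatial transforms.

## The statistical model

The core inferential step treats every patient as a single case compared
against a small control sample. At each voxel, with patient value $x$ and
control values $c_1,\dots,c_n$ (sample mean $\bar c$, sample SD $s$), the
Crawford-Howell t statistic is

$$ t \;=\; \frac{x - \bar c}{s\,\sqrt{\tfrac{n+1}{n}}}, \qquad
   \mathrm{df} = n - 1 . $$

Unlike a z-score against the control mean, the $\sqrt{(n+1)/n}$ factor and
the Student reference distribution account for the sampling error of a
small normative cohort. Voxels where $s = 0$ are flagged undefined and never
labelled. Thresholding is two-tailed at level $\alpha$ (Bonferroni-corrected
by the number of in-brain-mask voxels by default): $t > t_{\rm crit}$ labels
+1 (hemorrhage), $t < -t_{\rm crit}$ labels -1 (ischemia). The two-tailed
split with sign assignment reproduces the ternary semantics of detecting
hyper- and hypo-intensity at a common significance level; degrees of freedom
are $n-1$ as prescribed for the single-case t.

The working assumptions are (i) accurate spatial correspondence across
subjects, which the normalization cascade below is designed to deliver, and
(ii) approximate per-voxel Gaussianity of control intensities, which
Gaussian smoothing promotes. Near tissue interfaces (ventricles, brain
contours) assumption (ii) degrades for any sharp-interface anatomy -- there
the intensity response to anatomical variability is a sliding sigmoid, not
a linear map of a Gaussian -- and the elevated SD map partially absorbs
this. This is also why the method is least sensitive close to ventricles
and contours.

## The normalization cascade

Each scan (patient and control alike -- identical processing is essential,
because the normative model must see the same interpolation and smoothing
operators as the patient) passes through:

1. **Head extraction** (`strip_nonhead`): threshold-based clustering at
   0.1% of the maximum intensity, computed on intensities shifted by +1000
   so that air is zero (on the signed HU scale, 0.1% of the maximum would
   sit near 0 HU and discard parenchyma). Clustering is 26-connected
   component labelling; the largest component is the head.
2. **Rigid coregistration** (`coregister_rigid`): a 6-parameter fit to the
   template maximizing normalized cross-correlation over a coarse-to-fine
   subsampling schedule.
3. **Invertible intensity transform** (`transform_intensity`): HU in
   $[-1000,-100]$ map to $0$--$900$ (add 1000); HU in $(-100,100]$ map
   linearly onto $(900, 3100]$; HU above 100 map to HU + 3000. The printed
   endpoints force the middle slope to be exactly
   $(3100-911)/199 = 11$, so the map is continuous, strictly increasing and
   exactly invertible (integer HU round-trip with zero error). The
   transform expands the CSF/parenchyma contrast eleven-fold while
   compressing the air and bone extremes, which is what makes both the
   intensity-based segmentation and the deformable matching work, and it
   deliberately reduces the relative contrast of lesions so that the same
   pipeline normalizes stroke and control scans.
4. **Affine normalization** (`affine_normalize`): 12-parameter
   (translation, rotation, log-scale, shear) fit, same similarity machinery.
5. **Segmentation and skull stripping** (`segment_masks`, `skull_strip`):
   thresholds at mean $\pm$ 2 SD of the in-head soft-tissue intensity
   distribution define the ventricle mask (below) and the contour mask
   (above; this always includes bone). Stripping sets those voxels -- and
   everything outside the head -- to the background value 0 in scaled
   units, keeping lesioned voxels.
6. **Deformable normalization** (`nonlinear_normalize`): a demons-style
   multi-resolution registration estimated on the skull-stripped pair and
   applied to the unmasked image, so that the (possibly lesion-bearing)
   image is carried by a deformation estimated from stable structures.
7. **Reslicing** (`reslice`) at 1 mm isotropic over the bounding box
   $[-90,-126,-82]$ to $[90, 90, 108]$ mm (inclusive at both ends: a 1 mm
   grid has $181 \times 217 \times 191$ samples), trilinear interpolation.
8. **Gaussian smoothing** (`smooth_volume`), default 5 mm FWHM
   ($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2}) \approx 2.12$ mm),
   separable, constant-zero padding.

The control volumes then feed `control_model()` (voxelwise mean, sample SD,
cohort size, brain mask = voxels above background in every control), and
`delineate()` runs the cascade for a patient, computes the t map
(`crawford_howell_t`, also available as `predict()` on the model object),
thresholds it, and inverse-warps the ternary map to the native grid with
nearest-neighbour interpolation (labels stay in $\{-1,0,1\}$).

## Numerical and design choices

* **Similarity metric.** Normalized cross-correlation is the default:
  after the intensity transform, scan and template are effectively
  same-modality and NCC is a smooth objective for the quasi-Newton
  optimizer. Normalized mutual information (`metric = "nmi"`) is available
  for genuinely different intensity distributions. The similarity is
  evaluated at sub-voxel-jittered sample points (a regular sampling lattice
  has interpolation ripple that biases the optimum by up to half a voxel),
  restricted to in-field samples with a penalty below 50% overlap (the
  field-of-view edge of the moving image must not act as fake structure),
  and the reported before/after similarities are recomputed on the full
  grid rather than the optimizer's subsample.
* **Deformable model.** A small-deformation demons scheme: force
  $r\,\nabla f / (|\nabla f|^2 + (r/\kappa)^2)$ with $r$ the residual,
  $\nabla f$ the fixed-image gradient and $\kappa$ one (finest) voxel,
  which bounds each update at $\kappa/2$ mm; fluid smoothing of the update
  ($\sigma = 2$ level-voxels), light elastic smoothing of the field
  ($\sigma = 0.5$), three resolution levels (strides 4/2/1 at 30/40/25
  iterations). The field is confined to a feathered support mask of the
  stripped images: outside them there is no matching information, and an
  extrapolated field would perturb the skull that the affine step already
  aligned. Few coarse-level iterations matter more than many: at
  convergence the bounded residual force produces a slow parameter drift,
  so the schedule stops each level well before drift accumulates.
  Deformation inversion uses the fixed-point iteration
  $v \leftarrow -d(x + v)$ (20 iterations / 0.05 mm), on a stride-2 grid
  when inverting for label maps.
* **Segmentation moments.** The mean/SD of the 2-SD rule are estimated as
  median and MAD-scaled SD (identical for Gaussian intensities). Moment
  estimates are fragile here: a resampled scan carries partial-volume tails
  that inflate the plain SD several-fold relative to the unresampled
  template, which desynchronizes the strip masks of patient and template
  and derails the deformable step. Bone is excluded from the estimation
  window (not from the contour mask -- bone is always a contour) for the
  same reason. `estimator = "moment"` restores the literal rule.
* **One interpolation per stage output.** The rigid and affine sampling
  maps are composed so the affine-normalized image is interpolated once
  from the native scan.
* **Stage correlations.** The coregistered -> affine -> deformable
  correlation chain is measured on 5-mm-smoothed images over the template
  head mask. Unsmoothed voxelwise correlation on coarse grids is dominated
  by sub-voxel jitter of the one-voxel-thick skull ring and by blur
  differences between stages, and can decrease even when alignment
  improves.
* **Defaults** (`pipeline_config()`): 5 mm FWHM, $\alpha = 0.05$
  Bonferroni, 1 mm reslicing, 2-SD segmentation, 0.1% head threshold --
  the operating point selected by the simulated-lesion parameter sweep
  (`parameter_sweep()` reproduces that sweep on synthetic data). An
  optional minimum-cluster-size post-filter (`filter_clusters`, 1400
  voxels) is off by default; it is a visualization aid.

## The synthetic world

No real CT data ship with the package; every test runs on a generated
phantom world (`phantom_spec`, `make_phantom_template`,
`make_control_cohort`, `inject_spherical_lesion`,
`generate_simulation_grid`).

The template is an ellipsoidal head (brain semi-axes 68/86/62 mm centred
near the template origin) with gray/white parenchyma (36/30 HU), two
lateral ventricles and a thin CSF rim (2 HU), a skull shell (700 HU), air
at -1000 HU, blurred with a 2.5 mm FWHM point-spread kernel. Parenchyma
carries a smooth $\pm$8 HU modulation at 20 mm wavelength emulating
gray/white convolutional structure; without interior intensity structure
the deformable-recovery contract is unattainable for *any* intensity-based
registration (the aperture problem: on a homogeneous ellipsoid all
tangential motion is unobservable). Control subjects are the template
warped by a small random affine plus a band-limited random displacement
(max 3 mm -- a realistic residual anatomical variability after affine
alignment) with 4 HU Gaussian noise inside the head (typical brain-CT
noise). Lesions are hard replacements by
$\bar{I}_{\rm brain}(1 + \delta/100)$ inside spheres at the five published
MNI centres, radii 7/10/15/22 mm and $\delta = \pm 20/40/60\%$; the default
design crosses 5 scans x 4 radii x 6 contrasts = 120 cases.

What the phantom does *not* emulate: scanner physics (beam hardening,
4--5 mm slice anisotropy, metal artifacts), midline shift and mass effects,
atrophy, and real gyral anatomy. A green end-to-end test therefore
establishes that the pipeline recovers known lesions under realistic
geometry, contrast and noise -- not that it reproduces the published
real-data Dice values, which depend on an unavailable clinical cohort and
template.

Two phantom-world findings are worth stating plainly. First, with
realistic CSF contrast the ventricles sit well inside 2 SD of the soft-
tissue distribution, so the ventricle mask is nearly empty on the default
phantom and the CSF-free property of the stripped image is carried almost
entirely by the contour/bone mask; the segmentation tests therefore
construct their own scenarios (a Gaussian intensity volume, where the
ventricle fraction must be $\Phi(-2) \approx 0.0228$; and ventricles forced
4 SD below parenchyma, which must be covered at 95%). Second, per-voxel
Gaussianity across a deformed cohort fails within about one point-spread
width of every tissue interface -- an intrinsic property of sharp-interface
anatomy, not a generator defect -- so the normality property is asserted on
in-brain voxels with a locally flat template neighborhood.

## VLSM

`vlsm()` fits, at every voxel lesioned in at least 10 and spared in at
least 10 subjects, the linear model score ~ lesion indicator; the slope t
equals the pooled two-sample t (df $= n - 2$), and the family-wise
threshold is the empirical $(1-\alpha)$ quantile of the permutation null of
the maximum statistic (scores reshuffled across subjects, lesions fixed,
default 1000 permutations at $\alpha = 0.01$). One-tailed by default
(higher score = more severe deficit); `tails = "two"` uses max $|t|$. Note
a property of max-statistic nulls: even at $\alpha \to 1$ the threshold is
the *minimum of the per-permutation maxima*, which still exceeds most
per-voxel t values -- liberal alpha does not flood the map.

## Scale-down for routine testing

The paper-scale world is a 1 mm grid (7.5M voxels) with 72 controls. The
registration-heavy tests and acceptance checks run the identical pipeline
on the same bounding box at 3 mm with a 20-subject cohort; contrasts,
noise, smoothing and thresholds are unchanged. `pipeline_config()` defaults
remain at 1 mm.

## Known limitations

* Hypo-intensity cannot be distinguished from atrophy or chronic change;
  on real data the hypo-intense false-positive rate is an order of
  magnitude above the hyper-intense one.
* Sensitivity drops near ventricles and brain contours (inflated SD map)
  and for small, low-contrast lesions (smoothing blends them into the
  background).
* The demons registration assumes small deformations; gross mass effect or
  midline shift is out of scope.
* Age and other demographic covariates are not modelled; controls should
  be approximately age-matched.
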