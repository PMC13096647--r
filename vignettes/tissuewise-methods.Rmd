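---
title: "Tissue-wise PET/CT projections: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-wise PET/CT projections: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuewise)
```

## The problem

Whole-body FDG-PET/CT carries both anatomical (CT) and metabolic (PET)
information, but 3D volumes are expensive inputs for convolutional networks.
A practical compromise is to collapse each volume into a small set of 2D
projections.  A plain maximum-intensity projection (MIP) of the SUV volume,
however, superimposes every tissue along the ray: a faint lesion behind the
bladder or brain disappears.  The idea implemented here is to *decompose*
the CT into tissue compartments first — bone, lean soft tissue, adipose
tissue, and air — using fixed Hounsfield-unit (HU) thresholds, mask both the
CT and the SUV volume with each compartment, and project every masked volume
separately.  The network then sees ten registered channels
(`{original, bone, lean, adipose, air} x {CT, SUV}`) instead of one, which
preserves per-tissue contrast that a single projection destroys.

On top of this representation the package provides the full study loop:
target extraction from lesion annotations (total metabolic tumor volume,
lesion count), a compact densely-connected CNN for regression (TMTV, lesion
count, age) and binary classification (sex, diagnosis status), stratified
k-fold cross-validation, evaluation statistics with paired-model comparisons,
Grad-CAM saliency with cohort aggregation by sex, and a synthetic phantom
generator that makes every stage testable without any data download.

## Tissue decomposition

A voxel with Hounsfield unit $i$ is assigned to

* bone when $i \ge 200$,
* lean tissue when $-29 \le i \le 150$,
* adipose tissue when $-190 \le i \le -30$,
* air when $i < -190$.

The thresholds are implemented exactly as printed, which leaves the
intervals $(150, 200)$ and $(-30, -29)$ assigned to *no* compartment.  We
deliberately do not reassign these gap voxels: the masks are the method's
published definition, and fidelity wins over plausible intent.
`tissue_masks(ct, strict = FALSE)` reports how many voxels fall in the gaps
(on real CT, a fraction of a percent; on the synthetic phantoms, essentially
none).  Tissue channels are produced by multiplying CT and SUV with the
binary masks; masked-out voxels are therefore 0 in every channel, including
the CT ones, where 0 is *not* air.  This can invert contrast for the adipose
CT channel (fat is negative HU, background is 0); because the same
convention enters training and inference alike, it is harmless for learning,
but the channels should not be window-displayed as if they were CT.

## Projections and the collage

Projections are taken about the longitudinal (inferior-superior) axis.
$\Theta = 0°$ is the coronal view (rays along anterior-posterior) and
$\Theta = 90°$ the sagittal view (rays along left-right); both are computed
exactly.  Oblique angles rotate the transverse plane by $\Theta$ with
bilinear interpolation (the plane is padded to its diagonal first, so no
tissue is clipped) and then project as for $0°$.  SUV channels use MIP; CT
channels use the mean-intensity projection (meanIP).  One passage of the
source description writes the CT baseline as a MIP, while every results
table consistently labels CT channels meanIP; we treat the former as a typo
and use meanIP for CT throughout.

The meanIP denominator is the *entire* ray, background included.  The pixel
is then proportional to the integrated masked intensity, so a thicker bone
column projects brighter — the "amount of tissue" signal is preserved.  The
alternative (mean over in-mask voxels only) is available via
`mean_in_mask = TRUE`.  A consequence worth knowing: padding the plane for
oblique angles lengthens the rays, scaling full-ray means by a constant
factor per angle.  Ray *integrals* are rotation-invariant; tests compare
oblique to coronal projections on that basis.

Each channel's projections are normalized to $[0, 1]$ with fixed global
windows — CT $[-1024, 1500]$ HU, SUV $[0, 30]$ — rather than per-subject
min-max, so that a given pixel value means the same thing in every subject.
Per-angle projections are then laid side by side left-to-right and
zero-padded/center-cropped to a fixed canvas: $(512, 512)$ for up to two
angles, $(512, 1024)$ for four.  The per-angle placement boxes are recorded
on the collage and are identical across channels; saliency aggregation and
lesion-localization checks rely on them.

## Targets

TMTV is the labeled voxel count times the voxel volume (ml); it uses the
annotation mask only, with no SUV thresholding, matching the ground-truth
protocol of manually delineated lesions.  The lesion count is the number of
3D connected components of the mask.  The counting connectivity is not fixed
by the method description, so it is exposed as a parameter; the default is
26-connectivity (faces, edges, corners), the usual choice for PET lesion
blobs, and tests pin the behaviour of all three conventions (6/18/26).

## Network and training

The regression/classification network is a densely-connected 2D CNN written
directly in the package (R with C++ convolution kernels): an initial strided
convolution, dense blocks whose layer outputs are concatenated onto their
inputs, average-pool transitions, global average pooling, dropout 0.25, and
one output unit (linear for regression, logit for classification).  Two
scales exist.  The `"full"` scale reproduces the DenseNet-121 layout (four
blocks of 6/12/24/16 layers, growth 32, 1x1 bottlenecks, halving
transitions); it is instantiable but not practical to train on one CPU.  The
`"tiny"` scale (initial 16-filter convolution, two blocks of two 3x3 layers,
growth 12, ~40k parameters) is the scale every test uses.  Composite layers
are Conv-ReLU; batch normalization is omitted — at tiny scale it is
unnecessary and its omission keeps the backward pass simple and exactly
reproducible.  Dropout is applied to the pooled feature vector before the
linear head; the method description fixes the rate (0.25) but not the
placement.

Losses and optimization follow the protocol: smooth-L1 for regression,
binary cross-entropy for classification, Adam with learning rate $10^{-4}$,
weight decay $10^{-5}$, batch size 30.  These are the `train_config()`
defaults.  The epoch budget and stopping rule are not specified by the
protocol; we default to a fixed budget with a best-validation-loss
checkpoint.  Regression targets are z-scored internally using training-set
statistics (predictions are returned in original units), which keeps the
smooth-L1 transition point meaningful across targets with very different
scales (ml vs years).  For the tiny scale we found Adam at $10^{-3}$
converges in a practical number of epochs and use that in the test
configurations; the printed $10^{-4}$ remains the default.

Cross-validation is stratified by sex and cancer type via `make_folds()`:
subjects are shuffled within each stratum and dealt evenly into k folds
(remainders go to the currently smallest folds), so per-fold strata
proportions and fold sizes match the cohort within one subject.  Strata
smaller than k are merged into a pooled stratum with a warning.  Everything
(initialization, shuffling, dropout) draws from R's RNG under a single seed,
so a full run is bitwise reproducible.

## Evaluation statistics

Regression reports MAE, $R^2 = 1 - SS_{res}/SS_{tot}$, and Pearson's r;
classification reports the Mann-Whitney AUC (ties count one half) plus
sensitivity, specificity and precision at a 0.5 threshold.  Confidence
intervals are nonparametric percentile bootstrap over subjects (default 1000
resamples, seed-controlled); the source protocol reports 95% CIs without
naming a method, and the percentile bootstrap is the assumption-light
default.  CIs are computed on the pooled predictions, with a per-fold
breakdown attached, since the protocol does not say which; both are
available.

Two paired-model comparisons are implemented.  Steiger's Z compares the two
models' correlations with the shared ground truth (the overlapping-variable
case, with $r_{12}$ taken from the two prediction vectors), using Fisher
z-transforms and the Dunn-Clark covariance with Steiger's mean-correlation
simplification.  DeLong's test compares the paired AUCs through the
structural-components variance estimate.  Both are validated two ways: the
AUC equals an exhaustive pair-count oracle on all small inputs, and both
tests hold their nominal 5% type-I error within ±2 percentage points under
simulated nulls (2000 replications); the bootstrap CI covers a known true
MAE 95% ± 3% of the time over 500 replications.  Degenerate inputs are
handled explicitly: equal correlations give z = 0, p = 1 regardless of
$r_{12}$; identical score vectors give an AUC difference of zero with p = 1.

Continuous targets can additionally be summarized as a binned confusion
matrix (`binned_confusion()`); the bin edges used in the source figures are
not printed, so the default is ground-truth quantile bins with configurable
edges.

## Saliency

Grad-CAM is computed against the feature maps of the *first* convolutional
layer — unusually early for Grad-CAM, but that is what the method
prescribes, and at that depth the maps are still nearly at input resolution.
The channel weights $\alpha_k$ are spatial means of
$\partial \text{output} / \partial A^k$, the weighted sum is rectified,
bilinearly upsampled to the collage canvas, and max-normalized to $[0, 1]$
per map so that large-gradient subjects do not dominate cohort averages.

Cohort saliency in the original work aligned individual maps through a
deformable whole-body 3D registration before averaging.  That registration
framework is outside this package's scope; `aggregate_cohort_saliency()`
instead averages per sex directly in the shared padded canvas space.  For
the synthetic cohort — whose subjects share one grid and one body model —
this is exact enough; for real data it is a documented simplification, and
cohort maps should be read as coarse spatial tendencies only.

## The synthetic phantom cohort

`generate_phantom()` builds a head-to-mid-thigh body on the method's common
grid (96 x 96 x 160 voxels at 2.04 x 2.04 x 3 mm by default): two legs with
femurs, an elliptic torso interpolating hip-to-shoulder widths, a spine, two
lungs, a neck, and a head with scalp, skull, and an FDG-avid brain.  Tissue
HU are drawn per compartment — lean 40 ± 15, adipose −100 ± 20, bone
(age-dependent mean) ± 100, lung −800 ± 50, exterior air −1000 ± 30 — so
that with the default noise every compartment falls inside its threshold
interval with probability well above 0.95, and a noiseless phantom is
recovered exactly by `tissue_masks()`.  Background SUV is ~1 in lean tissue,
lower in fat and lung, ~4 in brain; PET noise is Gaussian on activity, a
deliberate simplification of Poisson/reconstruction noise that suffices for
pipeline testing.  PET volumes are emitted in Bq/ml with weight and dose in
the metadata, so the SUV conversion step is genuinely exercised
(SUV = activity × weight[g] / dose[Bq], activity assumed decay-corrected —
a convention, since acquisition details are out of scope).

Lesions are spheres with uptake drawn uniformly from SUV 5-15, placed in the
lean torso with a minimum separation so the requested count equals the
connected-component count of the emitted mask.  The total lesion volume is
lognormal (meanlog log 25 ml, sdlog 1, truncated to 2-300 ml), split among
1 + negative-binomial many lesions; the resulting cohort TMTV distribution
is positively skewed, echoing the heavy right tail of real cohorts at a
desk-compatible scale (real TMTV spans 0.1-2481 ml; a 96-voxel-wide torso
cannot hold multi-litre disease, so the range is scaled down, not the
shape).  Demographics mirror typical oncologic PET cohorts: dose ~N(315, 40)
MBq clipped to [150, 432], weight by sex, age ~N(60, 15) clipped to
[11, 95].  Age drives the subcutaneous adipose thickness and mean bone HU
monotonically, and sex drives shoulder/hip geometry and adiposity, so the
age and sex tasks have recoverable signal by construction.

What passing on phantoms does **not** show: the phantoms have no organs with
variable uptake, no attenuation or partial-volume effects, no respiratory
motion, no annotation ambiguity, and their anatomy-covariate links (age →
fat, age → bone HU) are clean monotone functions.  Learning-task results on
phantoms therefore validate the *pipeline* — that the representation
preserves the signal and the training loop can extract it — not clinical
performance.

## Problem sizes and numerical choices

The tests and the acceptance script run the learning tasks on a 460-subject
synthetic cohort (47% cancer-negative): TMTV regression trains on 200
cancer-positive subjects (150 epochs) and evaluates on the held-out
positives; diagnosis classification trains on 368 mixed subjects (25
epochs) and evaluates on the remaining 92.  Network inputs are the 512-pixel
collages block-averaged by a factor 8 to 64 x 64, which keeps a full run in
CPU-minutes; the block average preserves the mean and keeps lesion MIP
energy, at the cost of sub-voxel lesion outlines.  Statistical calibration
uses 2000 null replications per test and 500 bootstrap-coverage
replications.  Resampling uses trilinear interpolation with voxel-centre
alignment and clamped half-voxel edges, nearest-neighbour for labels;
out-of-grid samples take the modality background (−1024 HU for raw CT, 0
otherwise; masked channels carry background 0).  Oblique projection demands
isotropic in-plane spacing (true of the 2.04 mm common grid) and is refused
otherwise rather than silently distorting.

## Known limitations

* The full-scale network is provided as a layout, not a trained artifact;
  dataset-level results on the public cohort require GPU-scale training and
  are out of scope.
* Cohort saliency aggregation assumes a shared canvas geometry; with real,
  variably-sized subjects it blurs anatomy that deformable registration
  would align.
* `binned_confusion()` bin edges default to quantiles because the original
  figure edges are unpublished.
* NIfTI orientation matrices are not interpreted beyond the fixed axis
  convention; inputs are expected axis-aligned, as resampled pipeline data
  are.
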