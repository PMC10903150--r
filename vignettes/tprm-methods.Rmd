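---
title: "Topological parametric response mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological parametric response mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tprm)
```

## The problem

Chronic obstructive pulmonary disease progresses, on current evidence, from
healthy parenchyma through functional small airways disease (fSAD) to
emphysema. Parametric response mapping (PRM) classifies each lung voxel of a
co-registered inspiration/expiration CT pair by joint Hounsfield-unit (HU)
thresholds into normal parenchyma (Norm), fSAD (normal inspiratory density
with expiratory air trapping), emphysema (Emph) and parenchymal disease
(PD). Whole-lung percent volumes of these classes quantify *how much*
disease is present but not *how it is arranged*. This package implements
the topological extension (tPRM): local Minkowski functionals of each PRM
class — the volume density `V` and the Euler-Poincaré characteristic `χ` —
computed in a moving window, which together measure the extent and the
pocket-versus-mesh arrangement of each class, plus the downstream analyses
that make those maps useful: spirometric staging, cohort statistics, and a
patch-based sparse dictionary-learning classifier of fast versus slow FEV1
decline.

Clinical paired-CT datasets of this kind sit behind data-use agreements, so
the package ships a first-class synthetic module: paired-CT phantoms with
known voxel labels and cohorts with known progression labels, against which
every stage of the pipeline is tested.

## PRM classification

Lung voxels with both scans inside [-1000, -250] HU are classified as

* Norm: inspiration in (-950, -810], expiration ≥ -856;
* fSAD: inspiration in (-950, -810], expiration < -856;
* Emph: inspiration < -950, expiration < -856;
* PD: inspiration > -810;

everything else — out-of-range voxels, indeterminate voxels (inspiration
< -950 with expiration > -856) and the measure-zero boundary combinations
the printed inequalities leave unmatched (e.g. inspiration exactly -950) —
is Unclassified. We deliberately honour the inequalities literally instead
of closing a boundary by fiat; with floating-point HU the unmatched
boundaries are unreachable in practice, and the choice is recorded here
rather than silently interpolated. Percent volume divides each class count
by the *total* expiratory lung volume, so Unclassified voxels stay in the
denominator.

## Local Minkowski maps

`χ` is computed on the cubical complex formed by the union of closed unit
voxels (foreground 26-connectivity): `χ = n0 − n1 + n2 − n3`, the
alternating sum of vertex, edge, face and cube counts. Each cell is
attributed to the lattice point at its minimal corner, which reduces `χ` to
a sum over 2×2×2 neighbourhood configurations; the compiled kernel uses a
256-entry lookup table and is cross-checked in the test suite against an
independent brute-force cell enumerator on an exhaustive battery of
fixtures (single voxel χ=1, annulus χ=0, hollow shell χ=2, disjoint unions,
random blobs, and every window of a 31³ instance). Intuition: +1 per
isolated pocket, negative values for a coalesced mesh with tunnels, +1 per
enclosed cavity.

Maps are evaluated in a 21×21×21-voxel moving window on a grid of every 5th
voxel. At each grid node,

* `V = ν(class ∩ W) / ν(lung ∩ W)`, with `ν` the cube-cell counting volume
  measure (so the denominator is the Minkowski volume estimate of the mask
  in the same window, not the nominal window volume);
* `χ = χ(class ∩ W) / |lung ∩ W|`, normalised per masked window voxel.

Windows are clipped at the volume boundary without padding — normalising by
in-window mask content already compensates for partial windows. The grid is
anchored at the array origin (voxel index 1); nodes whose window contains
no lung voxels are invalid and are filled from their nearest valid
neighbours before trilinear interpolation to every lung voxel. Voxels
outside the grid hull take the nearest node's value. Surface area and mean
breadth are deliberately out of scope; only `V` and `χ` are computed.

Two invariants tie the maps back to classical readouts and are enforced in
the tests: the whole-lung mean of `V` per class equals the class's percent
volume / 100 (up to grid discretisation, tolerance 0.02), and `V` summed
over the four classes equals 1 in windows free of Unclassified voxels.

## The synthetic phantom

A phantom is an ellipsoidal "lung" (default semi-axes 0.42 of a 48³ grid at
0.65 mm isotropic spacing, a typical CT in-plane resolution that makes
cm-scale distance profiles meaningful) in which non-Norm classes are
planted as unions of spherical pockets:

* Pocket centres sit on a cubic lattice restricted to the lung. The
  `coalescence` parameter in [0, 1] interpolates the lattice spacing from
  more than one ball diameter (disjoint pockets, raw χ = +k) down to about
  1.55 ball radii. In that dense regime the balls fuse along lattice edges
  while leaving uncovered tunnels at the face diagonals, producing a
  connected mesh with strongly negative χ. This lattice construction makes
  the pocket→mesh inversion deterministic, instead of relying on the
  density regime of a random Boolean model.
* With a `class_fractions` target, the class is grown around its centres by
  nearest-centre distance ranking until the target voxel count is met
  exactly, so percent volumes match the targets to rounding. A fraction
  target that disjoint balls cannot realise geometrically degrades
  gracefully into a denser (more overlapping) arrangement — at high disease
  fractions fSAD *is* coalesced, which is the physiology the parameter
  encodes.
* `pocket_placement` chooses between a compact cluster around a random seed
  site ("clustered") and pockets scattered over the whole lung ("spread").
  Both preserve pocket count, radius, and hence whole-lung `V` and `χ`;
  the pair isolates purely local spatial signal for the ML comparison.

HU values are drawn uniformly inside each class's admissible joint
(inspiration, expiration) HU rectangle shrunk by `3·hu_noise_sd + 0.5` HU,
then perturbed by Gaussian noise. At zero noise every voxel pair lies
strictly inside its class region, so classification recovers the planted
labels voxel-exactly; at positive noise about 0.3% of voxels cross a
threshold, a controlled misclassification rate. The emphysema band
(inspiration in [-1000, -950)) is only 50 HU wide, which bounds the
admissible noise at roughly `sd < 8`; the cohort default is 5 HU.

What the phantoms do *not* emulate: airway trees, registration error,
scanner-kernel differences, HU calibration drift, or anatomically realistic
lobe geometry. Passing tests therefore demonstrate correctness of the
algorithms under known ground truth, not clinical performance on real CT.

## The synthetic cohort

`generate_cohort()` draws per-subject GOLD grades from the reference
distribution and spirometry/demographics from per-grade moments matching
the published clinical characterisation of a large multi-centre ever-smoker
cohort (truncated normals keep each draw consistent with its grade, so
`gold_classify()` round-trips). Progressor labels are assigned exactly:
`round(fast_fraction · n)` subjects are fast, and 5-year FEV1 values are
constructed so that `delta_fev1()` reproduces the label (fast iff
ΔFEV1/yr ≤ -60 ml/yr, boundary inclusive).

The link between imaging and outcome is the generator's `effect_size`: the
separation, in pooled within-class SD units, of the phantom's fSAD fraction
(SD 0.05) and coalescence (SD 0.15) between fast and slow progressors,
applied as a symmetric ±effect/2 shift around the grade-specific mean. At
`effect_size = 0` the two classes' phantom distributions are identical and
the classifier must perform at chance; at 3 the classes are well separated.
The alternative `signal = "local"` construction keeps all whole-lung
summaries identical between classes and moves only the pocket arrangement
(clustered in fast cases, spread in slow ones) — the regime in which a
patch-based model carries information a whole-lung-mean logistic regression
cannot.

## The progression classifier

Per case, random in-lung patches (≥ 50% lung voxels each) are extracted
from the four interpolated channels `V_Norm`, `V_fSAD`, `χ_Norm`, `χ_fSAD`
and vectorised channel-by-channel. Because `χ` values are two orders of
magnitude smaller than `V`, channels are z-standardised with moments
estimated on the pooled training patches and frozen into the model —
without this the `χ` channels would be invisible to the reconstruction
objective.

Training patches inherit their case's fast/slow label (the label-transfer
rule is the package's design choice). One dictionary per class is learned
by alternating orthogonal matching pursuit (Gram-matrix form, at most `T`
atoms per code) with atom-wise approximate K-SVD updates; atoms stay at
unit norm, dead atoms are re-seeded on the worst-reconstructed patch, and
the coding objective is non-increasing across iterations (tested). A test
patch is labelled by the dictionary with the smaller sparse-coding
residual; exact ties go to slow, the conservative majority-class choice. A
case's score is the fraction of its patches labelled fast, thresholded at
0.5 (configurable) for the hard call; the score feeds the ROC. The
comparison baseline is a logistic regression on the four whole-lung means,
trained on the same stratified split (35% train by default, per-class
counts rounded), with a lightly ridge-regularised fallback when the
training data are separable.

Feature ranking uses minimum-redundancy maximum-relevance with mutual
information on 8-quantile-binned variables; constant features have zero
relevance and rank last. The stability analysis retrains single-channel
models over 10 independent training-patch draws and reports the Gaussian
(mean, SD) fit of each channel's test accuracy.

## Problem sizes and numerical choices

The package's own test and demonstration runs use 48³ phantoms, the
standard 21/5 window/stride, 40 patches of edge 7 per case, 32 atoms per
dictionary, sparsity 3 and 8 learning iterations, and cohorts of up to 400
subjects — sizes chosen so a full synthetic study runs on a laptop-class
single core in minutes while leaving every algorithmic component at its
standard operating point. Dictionary defaults for larger studies (edge 21,
64 atoms, sparsity 5) are exposed as arguments. Numerical details worth
recording: OMP solves its least-squares steps on the atom Gram matrix with
a 1e-12 ridge; the -60 ml/yr progressor boundary is compared with a 1e-9
guard to absorb floating-point litre arithmetic; box-plot quartiles use
linear interpolation of order statistics (type 7) with whiskers at
Q1 − 1.5·IQR and Q3 + 1.5·IQR; Spearman p-values use the asymptotic
approximation appropriate at cohort sizes.

## Stepwise regression

Forward selection with entry p < 0.05 and removal p > 0.10 over the tPRM
candidates, with the compulsory covariate block (age, sex, race, BMI,
pack-years, CT vendor) forced into every model — thresholds chosen to match
the convention of mainstream statistical packages when the criteria are not
otherwise specified. Standardized β are computed on z-scored continuous
variables; model fit (adjusted R², SE of the estimate) is reported on the
original outcome scale. Categorical covariates are reference-coded factors;
a vendor with more than two levels therefore contributes one indicator per
non-reference level rather than a single coefficient.

## Quality control

Full multi-centre QC protocols are proprietary to their studies; the
package provides a minimal surrogate: a case fails when its expiratory lung
volume is at least its inspiratory volume (an erroneous volume change) or
when either volume is outside 1–10 L. Because a registered pair shares one
lung mask, the two volumes must come from the original segmentations and
are supplied as metadata; the synthetic cohort table carries plausible
nominal volumes for this purpose.

## Known limitations

* The phantom lung is a single ellipsoid; volumes on the synthetic grid are
  far below physiologic lung volumes, so the QC volume checks apply to the
  metadata volumes, not the mask.
* Window/interpolation discretisation biases the V-mean/percent-volume
  proportionality by up to ~0.02 on 48³ grids, and somewhat more when an
  entire class is concentrated in a single compact blob; the property tests
  use distributed (spread) lesion fields, the representative arrangement.
* The χ sign inversion is demonstrated on the generator's pocket/mesh
  regimes; real fSAD fields are not unions of equal balls.
* The dictionary learner is the standard OMP + approximate K-SVD pairing;
  it makes no claim of matching any proprietary implementation detail
  beyond the published method class.
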