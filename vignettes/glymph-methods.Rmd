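---
title: "Quantifying glymphatic MRI markers: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glymphatic MRI markers: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymph)
```

## What this package computes

The glymphatic system clears interstitial metabolic waste from the brain
through perivascular fluid exchange. Two MRI markers are in routine use as
proxies for its integrity:

* the **DTI-ALPS index** — *diffusion tensor image analysis along
  perivascular spaces*. At the level of the lateral-ventricle body,
  projection fibers run superior–inferior (z) and association fibers
  anterior–posterior (y), while the perivascular spaces run left–right (x),
  perpendicular to both. Water diffusivity measured along x in those two
  fiber regions therefore carries a perivascular component, and the ratio

  $$\mathrm{ALPS} = \frac{D_{x,\mathrm{proj}} + D_{x,\mathrm{assoc}}}
                         {D_{y,\mathrm{proj}} + D_{z,\mathrm{assoc}}}$$

  is near 1 when no preferential perivascular diffusion exists and rises
  with increasing flow along the perivascular axis. The four diffusivities
  are ROI means of the tensor diagonal elements over 5-mm spheres placed at
  template coordinates — projection (24, −12, 24) / (−28, −12, 24) and
  association (36, −12, 24) / (−40, −12, 24) — projected into subject
  space. Left and right indices are averaged into the subject-level
  measure.

* **EPVS morphometrics** — enlarged perivascular spaces are CSF-isointense
  tubular lesions, typically under 3 mm in diameter, scored in the basal
  ganglia (BG) and centrum semiovale (CSO). The package labels
  26-connected components of a binary segmentation, excludes structures
  shorter than 2 mm, and reports total volume, count, and regional volume
  fractions, plus Dice/recall/precision agreement between segmentations
  and rater references.

Because the clinical cohorts behind such studies are not public, the
package ships a fully ground-truthed synthetic phantom cohort generator.
Every quantitative claim the test-suite makes is a claim about recovery of
known truth from these phantoms.

## The phantom

**Geometry.** The default subject is a 64×64×40 grid at 1.5 mm isotropic
spacing (the DTI-like resolution; we fit tensors on the native DWI grid
rather than resampling). The world frame is MNI-like but shifted so the
template ROI coordinates above fall inside the phantom's fiber slabs; the
affine is stored with every volume, and all geometry runs through it
(0-based voxel indices, world = affine · index). Axis-aligned boxes define
brain, BG, CSO, midbrain, a projection-fiber slab and an association-fiber
slab; BG, CSO and midbrain are pairwise disjoint, and where the two fiber
slabs overlap the projection slab wins.

**Diffusion model.** The ALPS formula is inverted to plant a known index
$g$: projection-slab tensors are $\mathrm{diag}(g\,d_\perp,\ d_\perp,\
d_\parallel)$ and association-slab tensors $\mathrm{diag}(g\,d_\perp,\
d_\parallel,\ d_\perp)$, with $d_\perp = 0.4\times10^{-3}$ and
$d_\parallel = 1.4\times10^{-3}\ \mathrm{mm^2/s}$ (typical white-matter
perpendicular/parallel diffusivities); other brain tissue is isotropic at
$0.8\times10^{-3}$. All four ROI means then give exactly $g$, so the whole
imaging chain can be checked against truth. Signals follow the monoexponential
model $S = S_0 e^{-b\,g^\top D g}$ over one $b=0$ volume and 24
near-uniform directions (spherical Fibonacci set) at $b = 1000$ s/mm².
Noise is Rician — the standard model for magnitude MRI — at a configurable
SNR ($S_0/\sigma$, default 30); a Gaussian fallback and a noise-free mode
(`snr = Inf`) exist. Per-subject $g$ is drawn from a group-level normal
distribution.

**Lesion model.** EPVS lesions are tubes of radius 1.2 mm with uniformly
random orientation and center, rasterized to a target voxel count, planted
in BG or CSO (default 80% BG, matching the BG-dominant regional burden of
the condition studied), rendered dark on the T1-like and bright on the
T2-like volume. Two constraints keep the ground truth exact: lesions are
mutually separated by at least one voxel, so 26-connected labeling
recovers the planted count exactly; and every lesion has at least 2
voxels, which at 1.5 mm spacing guarantees a length of ≥ 3 mm, so all
planted lesions survive the 2-mm filter. Placement plants large lesions
first and retries random poses; under extreme crowding it concedes volume
in 2-voxel steps rather than failing the subject, and the recorded truth
is always what was actually planted. Single-lesion size is capped at 50
voxels and per-subject count at 60 (the regions' packing capacity; both
caps truncate < 2% of the upper tail and leave cohort medians unchanged).

**Cohort calibration.** Group configurations are calibrated from printed
cohort summaries: mean ALPS 1.308 (AD), 1.450 (aMCI), 1.570 (NC). The
published "±" values are treated as standard errors of the estimated
marginal means, so the generator's between-subject SD is SEM·√n — this
makes cohort-mean recovery a well-posed target. Lesion counts use a
rounded lognormal with log-median = log(printed median) and
σ = log(Q3/median)/z₀.₇₅; per-lesion volumes use the σ fitted the same way
from the printed *total*-volume quartiles, with the per-lesion log-median
set so that E[per-lesion volume] = printed total median / printed count
median. (Setting the per-lesion log-median to the printed total median
divided by count naively would inflate the cohort median total by the
lognormal mean–median gap, ≈ 25% at these σ; the expectation-matching
choice makes the generated cohort median converge to the printed value,
which we verify at n = 5000 scalar draws.) Cognition scores follow
MMSE = a + b·ALPS + ε with the slope set for a correlation of ≈ 0.55 with
the true index and the intercept chosen so group means match the printed
MMSE/MoCA summaries; scores are clamped to [0, 30]. Age, sex and education
are drawn independently of the imaging metrics from the printed
demographics (matching cohorts whose demographics do not differ between
groups), and total
brain volume is an independent covariate (N(1.45×10⁶, 1.2×10⁵) mm³).

**What the phantom does not emulate.** Real anatomy (boxes, not brains),
registration error (transforms are exact inputs; registration estimation
is out of scope), partial-volume effects at lesion boundaries (binary
rendering), bias fields and skull (inputs are assumed preprocessed), FLAIR
appearance, lesion-tensor interaction (lesions do not perturb the
diffusion signal), and human rater behavior (raters are stochastic
boundary editors). Passing tests therefore demonstrate the correctness of
the quantification chain, not segmentation or registration performance on
clinical data.

## Tensor fitting

Per masked voxel we solve the log-linearized model
$\ln S = \ln S_0 - b\,g^\top D g$ by unweighted least squares over all
volumes (a weighted pass with predicted-signal² weights is available
behind a flag). Non-positive samples — possible under the Gaussian noise
fallback — are dropped from that voxel's fit; if fewer than 7 samples
remain, the voxel is flagged invalid and excluded from all ROI means.
Eigenvalues are clamped below at 10⁻⁶ mm²/s and the tensor reconstructed
from the clamped spectrum where clamping fired; this keeps FA in [0, 1]
and ALPS denominators positive under noise. FA and MD use the standard
closed forms from the (clamped) eigenvalues; eigenvalues come from the
analytic trigonometric solution for symmetric 3×3 matrices, vectorized
over voxels.

At SNR 30 the per-subject ALPS measurement error of this chain is small
(bias ≈ +0.002, SD ≈ 0.013 on the default phantom) relative to the
between-subject SDs (0.14–0.20), so cohort means are dominated by the
generator's own sampling variability, as intended.

## ALPS extraction choices

Sphere membership is boundary-inclusive (voxel center within
diameter/2) — deterministic and faithful to the printed 5-mm diameter
without sub-voxel weighting. ROI means are arithmetic means over valid
voxels. The printed "left" coordinates carry positive x, contrary to the
common right-positive template convention; the defaults follow the printed
labels verbatim, and `laterality = "radiological"` swaps the hemisphere
labels. ROI projection into subject space is nearest-neighbour resampling
through a supplied affine (exact in synthetic mode); an empty projected
ROI is an error, mirroring the manual placement check such pipelines
require, and a projected voxel count off by more than 2× from the
template's (volume-adjusted) raises a warning.

## EPVS measurement choices

*Length* is not defined in the conventions this field inherits, so the
package defines it as the spread of member-voxel centers projected on the
lesion's first principal axis, plus one voxel edge; for a straight tube
this equals its end-to-end extent, and it is stable under small boundary
edits. The filter retains lengths ≥ 2.0 mm exactly ("shorter than 2 mm
excluded" read strictly). Connectivity is 26-connected, the most inclusive
standard choice; no installed package labels 3D components, so the
labeling is a BFS over the sparse voxel set. Regional fractions divide by
whole-brain volume and are reported per-mille (×10³): published BG
fractions around 0.2 are not compatible with a raw ratio of a few hundred
mm³ to a ~10⁶ mm³ brain, so the scale is exposed as a configurable
constant defaulting to per-mille. Agreement conventions: both masks
empty → all three metrics 1; exactly one empty → all three 0. For
intersection/union references, note that precision is monotone
*nondecreasing* in the reference set (its denominator is the prediction
size), so precision against the raters' intersection can only be lower
than against either rater — the tests assert the direction the arithmetic
dictates. The rule-based segmenter (T1 below / T2 above thresholds inside
the brain, optional 3-mm width cleanup) is a transparent stand-in for
learned segmentation models, which are deliberately not reproduced; its
default thresholds bracket the phantom's construction contrasts and are
user configuration on real data.

## Statistics

Each variable is routed by a per-group Shapiro–Wilk gate at α = 0.05:
parametric only if every group passes; groups with constant values route
nonparametric. The parametric branch is ANCOVA (linear model
`value ~ group + covariates`, partial F for the group factor) with
Bonferroni-corrected contrasts of covariate-adjusted group means
(via emmeans); default covariates are age, sex (coded 0/1) and education.
The nonparametric branch is tie-corrected Kruskal–Wallis with Dunn
z-tests, Bonferroni-corrected over the three pairs (composing Dunn with
Bonferroni is the common convention when both are named). Partial
correlation residualizes both variables on the covariates (with
intercept) and takes the Pearson correlation of residuals, p from t with
n − 2 − k df; Spearman is the Pearson correlation of tie-averaged ranks
with the t approximation; the sex test is Pearson chi-square without
continuity correction. Degenerate inputs (all values identical, zero
residual variance, zero margins) are errors, except the constant-group
Shapiro case above, which routes nonparametric by design.

## Problem sizes used in the checks

Distribution-level calibration is checked at n = 5000 scalar draws.
Full-size imaging recovery uses the calibrated group sizes (89/24/32) on the
default 64×64×40 phantom at SNR 30; ground-truth EPVS recovery uses the
same sizes with structural-only rendering; segmentation agreement uses 50
subjects; detection-rate properties use 100 cohort seeds at the
generator's scalar level, where the group comparison operates on exactly
the distributions the rendered cohort carries. The demonstration driver
in `analysis/02_alps_pipeline.R` renders a reduced 20/10/10 cohort as a
worked example; the full-size run lives in `scripts/acceptance.R` and the
acceptance tests.

## Known limitations

* Kruskal–Wallis power at the calibrated EPVS effect size (log-scale
  AD–NC shift ≈ 0.36 at σ ≈ 0.6–0.7, n = 89/32) is ≈ 0.8, so the omnibus
  EPVS-volume comparison is *not* significant in every simulated cohort —
  a property of the effect size, not of the implementation; the ordering
  of group medians is recovered essentially always.
* The chi-square approximation to the Kruskal–Wallis null is only
  accurate to a few hundredths of probability at total n ≤ 7; the tests
  compare it with the exhaustive permutation distribution on
  representative small datasets.
* Voxelization quantizes lesion volumes to 3.375 mm³ steps on the default
  grid; the cohort-median effect is ≈ 1%.
* The per-mille fraction scale and the mm³ volume unit for the printed
  medians are inferences from magnitudes, exposed as configuration.
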