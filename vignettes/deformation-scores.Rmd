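---
title: "Decomposing brain deformation into normal aging and disease-specific atrophy"
author: "dbmaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing brain deformation into normal aging and disease-specific atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Structural brain change in an aging cohort mixes two processes: the atrophy
everyone accrues with age, and disease-specific change (here, the pattern
associated with Alzheimer's disease, AD). `dbmaging` separates them on the
deformation fields themselves — deformation-based morphometry (DBM) — rather
than on tissue-density or Jacobian scalars.

All deformations are parameterized by stationary velocity fields (SVFs): a
time-constant vector field $v$ whose unit-time flow
$$\frac{d\phi^{(t)}}{dt} = v(\phi^{(t)}), \qquad \phi^{(0)} = \mathrm{id}$$
defines a diffeomorphic (smooth, invertible, fold-free) map
$\phi = \phi^{(1)} = \exp(v)$. The flow is computed by scaling and squaring:
scale $v$ by $2^{-k}$, add the identity, and compose the small map with
itself $k$ times (default $k = 7$; accuracy is validated in the tests against
a 1024-step explicit Euler integration of the ODE).

Two SVFs drive the analysis:

* **The one-year normal-aging field $v_0$.** Age-specific cognitively normal
  (CN) templates at a young and an old age (defaults 60 and 90 years) are
  registered — young template moving, old fixed — and the resulting pair SVF
  is divided by the age gap:
  $v_0 = v_{\mathrm{pair}} / (90 - 60)$. Aging is assumed linear over this
  range, so $v_0$ is constant across ages.
* **The subject field $v_{subject}$.** Each scan is related to the reference
  (60-year) template by a subject-specific SVF, either estimated by the
  built-in registration or ingested from an external tool.

At every voxel the subject field is orthogonally projected onto $v_0$:
$$AS = \frac{\langle v_{subject}, v_0\rangle}{\lVert v_0\rVert^2},
\qquad
ADS = \lVert v_{subject} - AS \cdot v_0 \rVert .$$
The **aging score** AS is in years relative to the reference age (the AS-age
line is expected to pass through 0 at age 60): positive values mean
faster-than-CN aging, negative slower. The **AD-specific score** ADS is the
magnitude (voxels) of the residual orthogonal to the normal-aging direction;
it is not proportional to age, which is why its scale differs from AS.

## Regions, outlier rejection and aggregation

Scores are aggregated as voxel-wise arithmetic means over four regions
derived from the template segmentations (FreeSurfer/SynthSeg label ids):
whole brain, ventricles {4, 14, 15, 43}, hippocampi & amygdala
{17, 53, 18, 54}, and the ventricle-edge map — the set difference between
the old- and young-template ventricle segmentations, i.e. the rim where the
aging deformation is concentrated and the homogeneous ventricle interior is
least informative. The edge map defaults to the symmetric difference;
because ventricles enlarge with age, the old-minus-young shell dominates and
a `growthOnly` flag restricts to it. A labelled region errors only when
*none* of its ids occur in the segmentation, so partial label conventions
are accepted.

Where $\lVert v_0\rVert$ is small, AS and ADS blow up. The guard is quantile
thresholding: within each region, voxels whose $\lVert v_0\rVert$ falls
below the quantile-$q$ value (linear-interpolation quantile, computed per
region; threshold applied as $\ge$, so $q = 0$ keeps every valid voxel) are
discarded. The quantile is chosen per region by sweeping
$q \in \{0, 0.1, \ldots, 0.9\}$ and maximizing the $R^2$ of the AS-versus-age
ordinary-least-squares fit in the CN group, ties going to the smallest
quantile (least data discarded). A hard floor `eps = 1e-8` voxels on
$\lVert v_0\rVert$ merely prevents division blow-ups; the quantile is the
real filter.

## The registration component

The package includes a classical multiresolution SVF registration (a
log-domain, fluid-like demons scheme): sum-of-squared-differences data term,
optionally restricted to a dilated segmentation mask to keep background
errors out; update direction = residual times warped-image gradient,
smoothed with a Gaussian of `sigmaFluid` (default 2 voxels); step size by
backtracking line search on the data term; three pyramid levels at scale
factors 4/2/1. It is deterministic — no stochastic sampling — so repeated
runs are bit-identical. Warping uses the pullback (spatial-transformer)
convention `warped(x) = image(phi(x))` with edge-clamped trilinear (or, for
labels, nearest-neighbour) resampling; composition is carried out on the
displacement view, which is far better behaved under edge clamping than
resampling raw coordinate maps.

Direction conventions matter for the sign of AS and are fixed as follows:
`registerSVF(fixed, moving)` returns the SVF whose flow warps *moving* onto
*fixed*; the template is the moving image both for the template pair
(old fixed) and for subjects (subject fixed). Under this convention a
subject deformed beyond the reference template ages *positively*.

On self-deformed phantoms with planted fields of about one voxel, the
stand-in reduces SSD by over 99% and recovers regional AS to within a few
percent in the ventricle-driven regions; small structures (the hippocampal
blobs, a few voxels across) retain a larger smoothing-induced bias, which is
why the recovery experiments assert on the ventricle regions. Learned
registration outputs can be substituted at any point via
`loadExternalSVF()`.

## Template sharpness (EFC)

Template quality is scored with the entropy focus criterion
$$EFC = -\sum_{i=1}^{N} \frac{B_i}{B_{max}}
\ln\frac{B_i}{B_{max}}, \qquad
B_{max} = \sqrt{\textstyle\sum_i B_i^2},$$
over in-mask voxels (any non-zero label is in-mask), with $0\ln 0 = 0$.
Sharper images score lower; all energy in one voxel gives exactly 0. The
normalization constant mapping EFC onto $[0, 1]$ is the entropy of the
uniform in-mask image, $\sqrt{N}\ln(N)/2$ — the unique choice that makes
both printed extremes (0 for one-hot, 1 for uniform) exact.

## The statistics layer

* **Age trends.** OLS of each regional score on chronological age, with
  $R^2$, the slope p-value and a 95% confidence band for plotting. A
  constant score is reported as slope 0, $R^2 = 0$.
* **ANCOVA age adjustment.** A common-slope additive model
  `score ~ age + group` is fitted, $\hat\beta_{age}(age - \bar a_{CN})$ is
  subtracted, and the CN mean of the adjusted scores is removed so CN
  centers at 0. The covariate centering point (mean CN age) shifts all
  groups equally and cancels in contrasts; an interaction (per-group slope)
  model was deliberately not used, since group-wise slopes are poorly
  identified at the small stage-group sizes this design targets.
* **Pairwise tests.** Independent two-sample t-tests on every pair of
  groups, Welch by default (`equalVar = TRUE` gives the classic pooled
  test — Welch is the safer default when only "independent t-tests" is
  specified), Bonferroni-corrected over the number of tested pairs. Groups
  with fewer than 5 scans (e.g. a CDR 2 stage with only four scans) are
  excluded from testing with a notice. Cohen's d uses the pooled SD with
  $n-1$ denominators regardless of the t-test variant; the sign is
  mean(first) − mean(second).
* **Bands.** Significance: ns $p>0.05$; * $0.01<p\le0.05$; **
  $0.001<p\le0.01$; *** $0.0001<p\le0.001$; **** $p\le0.0001$. Effect size
  on $|d|$: $[0.35, 0.65)$ medium, $[0.65, 0.9)$ large, $\ge 0.9$ very
  large; the boundary 0.9 itself is assigned to very large.
* Bonferroni correction is applied per region and per score; a joint
  correction across regions can be obtained by pooling the pair lists.

Under a simulated null the raw-p rejection rate at $\alpha = 0.05$ is
calibrated (checked at 1000 repetitions, $n = 30/30$, in the test suite).

## The synthetic cohort generator

Because the real pipeline upstream (template learning, segmentation,
large-cohort preprocessing) is out of scope, every experiment runs on
synthetic data with known truth:

* **Phantom** (default $48^3$ voxels; any size up to full scan dimensions
  works): a "brain" ellipsoid at intensity 0.6 containing two dark
  "ventricles" (labels 4/43, CSF-like intensity 0.1) and two "hippocampus"
  blobs (labels 17/53, intensity 0.4; the amygdala ids are merged into
  these blobs so the built-in region definitions apply). Intensities are
  edge-softened with a 0.8-voxel Gaussian; labels stay crisp. Structures
  must be nested and disjoint, which is validated.
* **Ground-truth aging field**: a radially oriented Gaussian shell on each
  structure boundary, enlarging ventricles and shrinking hippocampi under
  the pullback flow — the two cardinal macroscopic signatures of normal
  aging — peaking at `rate` voxels/year (default 0.05, i.e. 1.5 voxels of
  boundary motion over the 30-year template gap) and exactly zero outside
  the brain.
* **Subjects**: $v_{true} = AS_{true}\, v_{age} + ADS_{true}\, w + n$,
  where $w$ is a smooth random unit field made voxel-wise orthogonal to
  $v_{age}$ by per-voxel Gram–Schmidt (zero where $v_{age}$ is), and $n$ is
  smoothed Gaussian noise (per-component SD `noiseSigma` voxels, default
  0.05) emulating registration error. Noiseless subjects decompose back to
  the planted values exactly.
* **Cohorts**: a CN group (default 40 scans, ages uniform on 60–90, planted
  AS slope 1 year/year, between-scan jitter SD 1 year) plus CDR 0 / 0.5 /
  1 / 2 stages (25/25/20/4 scans) with stage-increasing planted AS
  accelerations (+2/+4/+6/+8 years) and ADS offsets
  (0.05/0.15/0.25/0.40/0.55 voxels). The CDR 2 group is deliberately tiny,
  matching the scarcity of moderate-stage scans in such cohorts, and is
  excluded from testing downstream. Everything derives deterministically
  from one seed.

What passing these experiments shows — and what it does not: the synthetic
phantoms have piecewise-constant tissue, no bias fields, no skull, no
photometric noise, and a deformation model drawn from the same family the
method assumes (a linear-in-age field plus a voxel-orthogonal disease
direction). Recovery on them validates the *machinery* (integration,
registration at desk scale, decomposition, selection, statistics), not the
biological claims on real MRI; real-data effect sizes require the external
template/segmentation/registration stack.

## Numerical choices and problem sizes

* All field algebra is in voxel units on 0-based indices; physical spacing
  is metadata only (inputs are assumed affinely pre-aligned and
  isotropically resampled). Physical-space algebra across differently
  oriented grids is out of scope.
* Interpolation is trilinear (nearest for labels) with edge-clamped
  coordinates; property tests assert on interior voxels, at least two from
  each face.
* Gaussian smoothing uses truncated, row-renormalized kernels, so constant
  fields are exactly invariant at boundaries.
* Deformations are stored as coordinate maps; the displacement view is used
  for composition and I/O.
* Default experiment sizes — $48^3$ grids, about 114 scans per synthetic
  cohort, 1000-repetition null calibration — were chosen so the full
  validation suite completes in minutes on a single CPU while leaving
  multi-voxel deformations representable; all are configurable upward.

## Known limitations

* Linear aging: $v_0$ is constant in age. An age-dependent $v_0$ would
  require a different normalization of AS/ADS and is not implemented.
* The ADS residual conflates disease-specific and subject-specific
  variability; no subject-level longitudinal modeling is attempted.
* The SSD-based registration stand-in under-recovers deformations of
  structures only a few voxels across (fluid smoothing bias); with learned
  or higher-order registration the scoring layer is unchanged.
* Aggregation happens in template space over template-derived region masks;
  subject-segmentation disagreement is not modeled.

## A minimal run

```r
library(dbmaging)

spec <- cohortSpec(nPerGroup = c(CN = 12L, CDR0 = 8L, `CDR0.5` = 8L,
                                 CDR1 = 6L), seed = 7L)
cohort <- makeCohort(spec, "cohort", shape = c(24, 24, 24), images = FALSE)
res <- runPipeline(pipelineConfig("cohort", "out", quantile = "auto"))
res$quantiles                     # chosen quantile and CN R^2 per region
subset(res$stats, score == "ADS") # age-adjusted pairwise comparisons
```

The same pipeline is scriptable from a shell through `exec/dbm`
(`dbm simulate`, `dbm register`, `dbm efc`, `dbm build-aging-field`,
`dbm region-mask`, `dbm score`, `dbm stats`, `dbm run`).
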