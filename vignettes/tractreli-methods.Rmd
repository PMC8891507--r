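---
title: "Template-based tractography clustering and its reliability metrics"
author: "tractreli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based tractography clustering and its reliability metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractreli)
```

## The problem

Diffusion MRI tractography reconstructs white-matter pathways as
*streamlines*: polylines in world-space millimetres. Grouping the
streamlines of a whole-brain tractogram into anatomically coherent bundles
(tracts), and doing so *consistently across subjects and sessions*, is a
prerequisite for any group-level analysis of tract geometry or of scalar
microstructure metrics such as fractional anisotropy (FA). tractreli
implements a template-based approach: a single template tractogram in a
common space is clustered once, and its cluster labels are then transferred
to any number of analysis tractograms by streamline similarity. The package
also implements the metric suite used to quantify how reliable the
resulting tracts are across a cohort, and a synthetic cohort generator with
planted ground truth so that every stage can be validated without access to
large tractography datasets.

## Distances and resampling

All streamline comparisons use the minimum average direct-flip (MDF)
distance. Both streamlines are first resampled to a common number of
equispaced points (default `n = 20`, endpoints included) by piecewise-linear
arc-length parameterisation — a spline is deliberately not used, since
nothing downstream needs more than the polyline geometry. For two resampled
streamlines $a$ and $b$,

$$
d_\mathrm{direct} = \frac{1}{n}\sum_i \lVert a_i - b_i\rVert,\qquad
d_\mathrm{flip} = \frac{1}{n}\sum_i \lVert a_i - b_{n+1-i}\rVert,\qquad
\mathrm{MDF} = \min(d_\mathrm{direct}, d_\mathrm{flip}),
$$

which makes the distance invariant to the arbitrary orientation in which a
tracking algorithm emits a streamline. MDF is symmetric and non-negative
but not a metric (the flip minimisation can violate the triangle
inequality), so the tests assert symmetry, flip invariance and identity of
indiscernibles rather than metric axioms.

## Template clustering

Two clustering routes operate on the same resampled template:

**Spectral clustering.** The full pairwise MDF matrix is computed (in
compiled code; this is the only $O(N^2 n)$ hot spot). Streamlines whose
mean distance to all others exceeds the grand mean by more than two sample
standard deviations are discarded as outliers. A Gaussian affinity
$w_{ij} = \exp(-d_{ij}^2 / 2\sigma^2)$ is applied — the configured "kernel
width" is read as $\sigma$ in this expression, since the source workflow
does not print the kernel formula; the convention is configurable. We then
form the symmetric normalised Laplacian
$L_\mathrm{sym} = I - D^{-1/2} W D^{-1/2}$, take the eigenvectors of its
$k$ smallest eigenvalues, row-normalise the embedding (the Ng–Jordan–Weiss
variant), and run k-means. The embedded k-means uses k-means++ seeding with
10 restarts under a fixed seed: plain random starts routinely land in
split/merge local optima on well-separated embeddings, while ++ seeding
recovers planted partitions exactly across seeds. Cluster ids are made
canonical (descending size, ties by lowest member index) so runs are
comparable.

**QuickBundles.** A single pass in input order: each streamline is compared
(MDF) to every existing cluster centroid and joins the nearest one if that
distance is below the threshold, flipping itself first when its flipped
orientation was closer; otherwise it seeds a new cluster, unless the
cluster cap is reached, in which case it joins the nearest centroid
unconditionally. Centroids are exact running means of the aligned member
points, not approximations. Assignment ties break to the lowest cluster id,
so the procedure is deterministic given the input order; when bundle
separation is much larger than the threshold the result is also
order-invariant, which the tests assert by shuffling.

Default parameters follow the reference workflow: whole-brain $k = 800$
with an 8 mm kernel/threshold, U-shaped tracts $k = 500$ with 6 mm, and a
20,000-streamline labeled subsample for propagation. All are configurable;
the demonstration cohort uses $k$ equal to its 12 planted bundles because
$k$ far above the true bundle count merely shreds bundles into fragments
on a toy template (the reference values were chosen by visual inspection
of 10M-streamline whole-brain templates).

## Label propagation

Analysis tractograms are resampled to the template's point count and each
streamline receives the label of its nearest template streamline by MDF
(ties to the lowest template index). Following the source workflow, no
rejection distance is applied by default — every streamline is labeled —
but an optional cutoff marks distant streamlines with the sentinel `-1`.
Template subsampling before propagation is uniform without replacement; a
stratified per-cluster option exists because the source does not state
whether its subsample was stratified.

## U-shaped (superficial white matter) streamlines

Short-range U-fibers are extracted from whole-brain tractography by
geometry alone: with $L$ the arc length and $D$ the endpoint (chord)
distance, a streamline is kept when $D < L/\pi$ — the chord is less than
roughly a third of the length, i.e. the path curls back on itself — and
its length lies within 20–80 mm, and it does not cross the sagittal
midline plane ($x = 0$ in template space, configurable). The printed
constraint in the source workflow bounds $D$ by 20–80 mm while its prose
calls these "streamline length constraints"; we bound $L$ by default
(matching the U-fiber literature the constraint derives from) and expose
`boundOn = "endpoint"` for the alternative reading. Points exactly on the
midline belong to neither hemisphere. Tract endpoints can be assigned to
parcellation labels by nearest labeled voxel centre within a 4 mm radius,
with per-tract-end majority vote and ties to the lowest label id.

## Reliability metrics

For each tract (cluster) and cohort:

- **Centroid distance.** Each subject's tract centroid is the per-point
  mean of its orientation-aligned members; the cohort average centroid is
  the aligned mean of subject centroids; each subject's distance to it is
  the MDF distance. At zero between-subject jitter this is exactly 0, and
  it increases strictly with the generating jitter SD (a property test).
- **Weighted Dice (wDSC).** Each streamline is upsampled so consecutive
  points are closer than half the smallest voxel edge (0.45× by default,
  configurable) and counted once per voxel it touches; the density map is
  the per-voxel fraction of the tract's streamlines. For two maps $A, B$:
  $\mathrm{wDSC} = (\sum_{v'} A_{v'} + \sum_{v'} B_{v'}) / (\sum_v A_v +
  \sum_v B_v)$ with $v'$ over the voxels where both are positive. Two
  empty maps score 0 by convention (logged). The cohort value is the mean
  over unordered subject pairs; subject-vs-template is a config option
  since the source is silent on the pairing.
- **Along-tract ICC.** The scalar volume is sampled by trilinear
  interpolation at each resampled point of each aligned member, averaged
  per sample index into a tract profile. Across subjects (rows) × samples
  (columns), agreement is the two-way random-effects absolute-agreement
  ICC, single-measurement form ICC(A,1) by default (the source names only
  the model, not single vs average; ICC(A,k) is exposed). The 95% CI uses
  the standard F-based interval. Perfect inter-subject agreement (zero
  between-subject and residual variance, e.g. identical profiles) is a
  degenerate case reported as ICC = 1 with a flag.
- **Streamline count CV.** Sample SD over mean × 100%; a zero mean is
  reported missing with a zero-count flag. Poisson($\lambda$) counts
  recover $100/\sqrt{\lambda}$% in simulation.
- **Inter-metric correlations.** Spearman rank correlations (average ranks
  on ties) between all metric pairs across tracts, streamline counts
  log-transformed first, two-sided p-values, Benjamini–Hochberg adjustment
  across the pairs tested. Pairs with missing values drop rows listwise;
  constant columns are reported as missing rather than fabricated.

Tracts absent from a subject are excluded from that subject's centroid,
overlap and profile computations and tallied in a missing-tract report;
their zero counts still enter the count/CV column, which is what a
"tract not reliably identified" flag should reflect.

Sample standard deviations ($n-1$) are used throughout (outlier rule, CV).

## The synthetic cohort generator

The generator emulates what the pipeline needs from a registered
multi-subject tractography study, nothing more. A bundle is a parametric
centroid curve (line, circular arc, or cubic Bezier) densely sampled
(≥ 50 points); each streamline is the curve under a rigid isotropic
Gaussian translation (`dispersionSd`), optionally with small per-point
jitter (`pointJitterSd`, default 0 so that the dispersion parameter is
cleanly recoverable), and half the streamlines are emitted reversed to
exercise flip handling. Subjects differ by a per-bundle rigid translation
drawn with SD `subjectJitterSd` and by multiplicative count noise
`U(−countJitter, +countJitter)`; the dispersion draws themselves are seeded
per bundle, not per subject, so zero jitter produces byte-identical
subjects — the degenerate cohort every end-to-end test pins its
expectations on. U-shaped bundles are arcs validated at construction
against the U-fiber constraints (fail fast rather than generate unusable
ground truth). Scalar volumes are rendered as constant fields, linear
gradients, or per-bundle plateaus on a background (a crude stand-in for FA
contrast).

Randomness derives from one root seed with counter-offset streams per
(subject, bundle), so adding a bundle or subject never perturbs existing
coordinates.

The default demonstration cohort is 15 subjects, 12 bundles (8 long-range
Bezier bundles and 4 U-shaped arcs, balanced across hemispheres), 100–300
streamlines per bundle, 1 mm dispersion, 1 mm subject jitter, 10% count
noise, on a 2 mm isotropic 80×96×80 grid. These sizes were chosen so a
full dual-method run completes in about a minute while keeping all twelve
bundles separable by ≥ 30 mm — large against both the dispersion and the
8 mm threshold, which is the regime in which clustering recovery is
provable rather than probabilistic.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: curving fanning geometry with partial bundle
overlap, false-positive streamlines from probabilistic tracking,
registration error beyond rigid jitter, realistic FA gradients within a
bundle, and bundle counts in the hundreds. Results on the synthetic cohort
validate the implementation, not the anatomy. One visible consequence: the
rendered scalar field is shared by all subjects, so the demo cohort has no
between-subject scalar variation and its along-tract ICC is near zero —
correctly, since ICC rewards consistent between-subject differences, which
the generator does not plant in its volumes (the ICC recovery tests
therefore simulate profile matrices with known variance components
directly).

## Numerical choices and degenerate inputs

- Resampling drops zero-length segments and errors (naming the streamline
  index) on fully degenerate streamlines.
- Voxel membership uses 0-based indices with world = affine·(i,j,k,1)ᵀ and
  nearest-integer rounding; density upsampling converges to exact segment
  traversal as the step shrinks.
- Outlier pruning can in principle discard everything (error, named as a
  degenerate configuration); re-running pruning on its own output may
  discard more — no idempotence is claimed.
- `k` exceeding the available streamlines is a clean error; `k` equal to
  the streamline count degenerates to singleton clusters.
- Spectral clustering errors on asymmetric affinities and on zero-degree
  rows (naming the row).
- wDSC on two empty maps, CV at zero mean, ICC under perfect agreement:
  all defined conventions (0, missing-with-flag, 1-with-flag) rather than
  NaN propagation, and all logged.

## Known limitations

MDF-nearest propagation assigns every streamline, so garbage streamlines
in an analysis dataset inherit a label unless the optional rejection
cutoff is enabled. The along-tract profile assumes point-index
correspondence across subjects, which degrades for tracts whose members
terminate at very different anatomical points. The spectral route holds
the full distance matrix in memory (fine to ~20k streamlines; the
reference workflow's 20,000-streamline subsample exists for the same
reason). The TRK reader supports version-2 headers with a valid
`vox_to_ras` affine only.
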