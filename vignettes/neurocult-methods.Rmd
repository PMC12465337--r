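---
title: "Quantifying neuronal culture development from longitudinal live-cell images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuronal culture development from longitudinal live-cell images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Stem-cell-derived neurons imaged daily over weeks reveal how a monolayer
culture matures: neurites extend, branch and fasciculate into bundles, and
somata migrate into compact clusters. Repeated fluorescence excitation is
itself a stressor (phototoxicity, largely via reactive oxygen species), so
cultures can also bleach gradually or die abruptly. `neurocult` provides the
quantification side of such an experiment: it turns a time-course of
single-channel fluorescence images — organised by plate, condition, well and
day — into per-well trajectories of five structural metrics plus mean
fluorescence, summarises each trajectory by its area under the curve (AUC),
and tests culture factors (medium, laminin substrate, seeding density) with
a factorial regression.

Because real screens of this kind are far too large to ship with a package
(a 33-day screen at 64 fields of view per well across 8 conditions is
118,272 images), every stage is exercised against a synthetic culture-image
generator with complete ground truth.

## Metrics

All metrics are computed per image on binary soma and neurite masks. The
package's deterministic classical segmenter (`segment_culture()`) produces
these masks from a preprocessed image; masks from an external pixel
classifier can be substituted via `ingest_masks()` and flow through the
identical downstream code.

**Neurite length.** The neurite mask is thinned to a one-pixel-wide
skeleton and the metric is the number of skeleton pixels. Pixel count is
the metric's definition, not an approximation: diagonal steps are
deliberately not corrected by $\sqrt{2}$, so lengths are comparable only
across images processed with the same convention (which is all this
pipeline needs). Thinning uses the Guo–Hall two-subiteration parallel
scheme, followed by a clean-up pass that removes any residual $2\times2$
solid block; this choice loses at most about two pixels at the free end of
a thick bar, against three or more for the plain two-condition scheme.

**Branch points.** A junction is a skeleton pixel with at least three
skeleton neighbours (8-connectivity). Thick junctions thin to small
clusters of such pixels, so 8-connected clusters of junction pixels are
merged and counted once (`merge = TRUE`, switchable). The reported metric
is branch points per skeleton pixel, which lies in $[0, 1]$ and is
undefined (missing, not zero) for an empty skeleton.

**Disaggregation Index.** With $s_0$ the average soma object area at the
first imaging day (user-settable; by default measured from day 1, making
the day-1 value exactly 1), $m_n$ the number of soma objects and $a_n$
their total area at day $n$:

$$DI_n = \frac{s_0\, m_n}{a_n}.$$

Somata fusing into clusters reduce $m_n$ faster than $a_n$, so organised
aggregation drives DI down; young, individuated cultures sit near 1.

**Cluster Density Factor.** With $m_0$ the soma count at the first imaging
day and $p_n$ the summed perimeter of soma objects at day $n$:

$$CDF_n = \frac{m_0}{p_n}.$$

Compact clusters have little total perimeter, so CDF rises as the culture
condenses. Perimeter is counted as exposed pixel edges (a pixel-edge walk),
not a Crofton-style estimate: CDF only requires a convention that is
consistent across timepoints, and the pixel-edge count is exactly
reproducible and cheap to verify against a brute-force oracle. Soma objects
are 8-connected components; objects touching the image border are retained,
since a tiled whole-well mosaic would otherwise systematically lose
boundary cells.

**Neurite coherency.** Local orientation alignment is measured by the
structure tensor: with $\lambda_1 \ge \lambda_2$ the eigenvalues of the
Gaussian-smoothed tensor averaged over a region, coherency is
$(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2) \in [0,1]$ — 1 for perfectly
parallel fibres, 0 for isotropic texture, and defined as 0 for a
gradient-free (constant) region. `region_coherency()` applies this in a
region-based configuration: around each soma object an annulus (the object
dilated by `reach`, minus the object) is divided into angular sectors about
the centroid; sectors with at least `min_cover` neurite coverage contribute
the coherency of the tensor averaged over their neurite pixels; sector
values average per object with equal weight, and object values average into
the image-level value.

The region geometry is a declared default, not an inference: reach 30 px
(about 18.6 µm at the 0.62 µm pixel size of the instrument this workflow
targets), 8 sectors, minimum coverage 0.02, tensor smoothing $\sigma=2$ px.
All four are configurable. Equal sector weighting (rather than weighting by
neurite pixel count) was chosen so a sparse sector with a single clean
bundle counts as much as a dense one. On large screens coherency is
restricted to a representative subset of 9 fields of view per well,
uniformly spaced on the mosaic: along an axis of $n$ tiles the selected
positions are $\lfloor (i-\tfrac12) n/3 \rfloor + 1$ for $i = 1,2,3$ — the
centres of thirds — kept identical across days.

## Trajectories, death events and AUC

Per-well daily values are the mean over that well's fields of view. Each
well's series is normalized to its first imaging day, so trajectories start
at 1 and AUCs compare fold-changes. A culture is declared dead at the first
day whose mean fluorescence drops *strictly more than* 10% below the
previous day's (the threshold is configurable); steps with a zero previous
value are skipped and logged. The AUC is the trapezoid rule over actual day
spacing, truncated before the death day — the culture is non-viable *at*
that timepoint, so the death-day observation is excluded by default
(`include_death_day` restores it). Fewer than two surviving timepoints
yield a missing AUC. The normalized series is the default AUC input; the
raw series is available via `use_normalized = FALSE`.

## Factorial analysis and network score

Per-well AUCs of each metric are modelled by ordinary least squares with
three main effects (medium, laminin, seeding density), their three two-way
interactions, and plate as a categorical nuisance covariate. Factors use
treatment coding with reference levels NB medium / mouse laminin / low
density, so each coefficient reads as the effect of switching to BPI /
human / high. Benjamini–Hochberg correction is applied across the six
effect terms of a fit. The step-up adjustment is monotone (adjusted values
never fall below raw ones and preserve order) but not idempotent in
general — re-adjusting an adjusted vector can raise tied groups further —
so no such claim is made or tested beyond fully-tied cases.

The network score ranks conditions by mean AUC separately for CDF and
coherency (rank 1 = lowest; ties share the mean rank), then sums the two
ranks; a higher summed rank indicates a condition whose cultures both
cluster and fasciculate more, i.e. more mature network formation. The score
is invariant to any strictly monotone transform of either metric — only
orderings matter.

## The synthetic culture generator

`generate_timecourse()` emulates the phenomena the metrics are designed to
detect, with every ground-truth quantity recorded:

* **Somata** are Gaussian-profile discs (radial $\sigma = 2R/3$, support
  truncated at the radius $R$, $R \sim N(5, 1)$ px by default) rendered at
  integer centres so a disc's pixel footprint is translation-invariant.
  Each day, positions contract toward fixed cluster centroids by the
  `cluster_attraction` rate; discs that come into contact merge into one
  connected object. Merging is emergent mask connectivity rather than an
  explicit overlap rule — at the mask level, where DI and CDF operate, the
  two are equivalent, and connectivity guarantees the object count never
  increases.
* **Neurites** are anti-aliased quadratic Bézier curves about 2–3 px wide,
  elongating by `neurite_growth_rate` px/day. One global bundle direction
  is drawn per culture; per-cluster and per-neurite angular deviations and
  the per-neurite bend amplitude all scale with
  $1 - \text{fasciculation\_strength}$, so 0 gives curved, isotropically
  oriented neurites and 1 gives straight, fully aligned bundles (the
  ground-truth orientation field then has circular variance 0).
* **Intensity.** Somata render at amplitude 1, neurites at 0.7, composited
  by maximum over a constant background of 0.02, scaled by the day's
  amplitude $A_d = 0.8\,(1-b)^{d-1}$ with bleach rate $b$, multiplied by
  $1-\text{death\_drop}$ from the death day on, plus Gaussian noise. The
  recorded ground-truth "true mean intensity" is $A_d$ itself — the
  intensity scale of the foreground — which makes the bleaching decay
  exactly $(1-b)$ per day even while the growing neurites change the
  foreground's composition.

Default study conditions (192×192 px frames, 25 somata, 3 neurites per
soma, attraction 0.15/day, bleach 5%/day, noise 0.01) are what a
moderate-density culture at this pixel scale looks like to the segmenter;
tests and examples that need a specific phenomenon (a death event, a
fasciculation sweep) set those parameters explicitly. The generator
emulates geometry, bleaching and death; it does **not** emulate uneven
illumination, debris, focus drift, or the texture statistics of real
fluorescence images, so passing recovery tests demonstrate the pipeline's
correctness on well-posed inputs, not segmentation robustness on difficult
real data — that is what the external-mask ingestion path is for.

The amplitude separation between somata (1.0) and neurites (0.7) is what
makes a purely classical segmentation viable: the width-based split
(morphological opening) cannot by itself distinguish a soma from a thick
neurite bundle that stays attached to it, so opened foreground is further
required to lie within `core_reach` of a bright core (≥ `core_frac` of the
image maximum). With these defaults the segmenter recovers synthetic ground
truth at Dice ≥ 0.9 (soma) and ≥ 0.8 (neurite) across seeds, days and
fasciculation levels.

`generate_factorial_dataset()` draws per-well AUCs directly from the
factorial linear model (chosen effects, plate offsets, Gaussian noise) for
testing the statistics layer in isolation.

## ROS quantification

The CellROX-style oxidative stress readout is reproduced arithmetically on
synthetic two-channel z-stacks: probe intensity is summed along z per
pixel, averaged within the nuclei mask (defined on the 2-D footprint and
applied to every slice — the projected-footprint convention), normalized by
nuclei count, and background-corrected by subtracting the negative
control's normalized mean. Nuclei counting replaces a commercial spot
detector with Laplacian-of-Gaussian blob detection at the same fixed
physical diameter (5.83 µm XY, converted by the pixel size, 1.25 µm for
these stacks); the peak threshold is relative to the maximum response, so
counts are invariant to global intensity scaling. The group comparison is a
standard linear mixed model (condition fixed, plate random, FOV replicates
as observations) delegated to `lme4`.

## Numerical choices and degenerate inputs

* Bit conversion rounds half-up; a constant 32-bit image maps to all
  zeros (documented, not an error). Min–max rescaling of a constant image
  warns and returns zeros.
* Coordinates are (row, column), 1-based, as R matrices index; masks share
  the image grid exactly.
* Connectivity is 8-connected throughout (somata, skeletons, junction
  merging); `label_components()` implements exact iterative minimum-label
  propagation and is verified exhaustively against a flood-fill oracle on
  all 65,536 4×4 grids.
* Zero denominators (empty masks, zero baselines, zero nuclei) produce
  missing values with warnings, never silent zeros — except mean
  fluorescence over an empty mask, which is defined as 0 with a warning
  because a fully dead frame is a legitimate observation.
* In pathological lattice-like masks a 2×2 block can survive thinning with
  no locally simple pixel; the clean-up then removes a pixel that keeps the
  global component count, or failing that one pixel regardless. Thinness is
  therefore guaranteed; topology, in that degenerate case only, is not.
* All randomness flows from a single seed; per-well seeds are derived
  deterministically and kept within 32-bit range. Identical configs give
  bit-identical CSV outputs.

## Problem sizes used in tests

The test-suite exercises the pipeline at desk scale: 96–192 px frames,
3–6 day series, 8-condition screens with 2 wells per condition, 200
replicates for factorial parameter recovery at 50 wells/condition, and
5-point sweeps for monotonicity properties. These sizes make every
property cheap to recompute while leaving all algorithmic paths identical
to a full-scale run; only the grid dimensions change.

## Known limitations

* DI and CDF assume the baseline scan is representative ($s_0$, $m_0$ are
  fixed per well); cultures whose cell count changes for reasons other
  than clustering (e.g. proliferation) violate that assumption.
* The death rule reacts to any >10% intensity drop between successive
  scans, including artefacts such as a focus failure.
* Skeleton length in pixel count under-measures diagonal runs relative to
  Euclidean length; comparisons across rotations of the *same* structure
  are stable to ~5%, but absolute lengths are convention-bound.
* The classical segmenter is tuned to the generator's contrast structure;
  for real Incucyte-class data an externally trained classifier via
  `ingest_masks()` is the recommended path.
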