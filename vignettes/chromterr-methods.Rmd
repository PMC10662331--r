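---
title: "Quantifying chromosome territory organization with chromterr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosome territory organization with chromterr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromterr)
```

## The problem

Whole-chromosome paint probes label the territory a chromosome occupies in
an interphase nucleus. Comparing territory organization between cell states
— for instance proliferating myoblasts, differentiated myotubes and
rhabdomyosarcoma lines — requires turning two-channel confocal stacks
(DAPI counterstain + chromosome paint) into per-nucleus numbers: nuclear
shape, how much of the nucleus the territory occupies, how peripherally it
sits, how dense its DNA is relative to the whole nucleus, and whether it
aligns with the nuclear major axis more often than chance would allow.

chromterr implements that measurement chain as composable functions plus a
synthetic scene generator with exact ground truth, so every stage — and
every statistical claim built on it — can be verified without microscopy
data.

## Measurement model

**Projection.** Analysis runs on 2-D maximum-intensity projections. Nuclei
in adherent myogenic cultures are flat relative to their lateral extent and
territories typically span most of the z-range, so a projection loses
little and makes all downstream geometry planar.

**Nuclear segmentation.** The DAPI projection is smoothed with a
non-local-means filter (patch radius 1, search radius 3) to normalise
staining, thresholded with the Kapur maximum-entropy criterion, closed with
a radius-2 disc (a 2-pixel dilation followed by a 2-pixel erosion, undoing
the boundary effect of the normalisation), and labelled. Components larger
than 10,000 px or touching the image frame are excluded; a configurable
debris floor (default 500 px, disableable) removes specks. Adjacent nuclei
that merge into one component are tolerated, not split.

The Kapur criterion picks the level maximising the summed Shannon
entropies of the two classes it induces. Two numerical details matter.
Ties (which occur whenever the histogram has an empty gap between classes)
break toward the lower level, so masks are reproducible bit-for-bit. And
the criterion only separates background from signal when the background
class retains measurable entropy; the auto-strength of the smoother is
therefore set to half the robust noise estimate, which evens out staining
without flattening the background noise floor the threshold relies on.

**Territory segmentation.** The paint projection is median-filtered over a
2-pixel radius; the Kapur threshold is computed from the histogram of
pixels inside the nuclear-mask union (the "confine to nuclear signal"
reading of the otherwise-unnamed partitioning step — the original
description pairs the entropy threshold with a partitioning step whose
algorithm is not standard; restricting the histogram to nuclear pixels is
the interpretation adopted here, exposed so it can be changed). Components
with area in [100, 10,000] px (inclusive bounds) are kept. Each territory
is assigned to the nucleus containing its centroid, or to the nucleus
holding at least half its pixels; otherwise it is flagged and excluded.

**Morphometry.** Axis lengths come from the moment-equivalent ellipse of
the binary mask (full axis = 4·sqrt(eigenvalue) of the second central
moments), the convention of mainstream cell-morphometry software;
eccentricity is sqrt(1 − (minor/major)²); centroids are unweighted.
Orientation is reported in the mathematical convention (counter-clockwise
from +x), folded to [0°, 180°), so image-coordinate handedness is invisible
to users.

**Radial rings.** Each nucleus is partitioned into six rings of equal
width in the normalised distance-to-edge coordinate
ρ = 1 − d_edge/max(d_edge), ring 1 innermost. This definition is exact for
arbitrary (non-elliptical) masks, partitions the mask exactly (half-open
bins, ρ = 0 to ring 1), and is shared verbatim by the generator, so truth
and measurement live in one coordinate system. Equal-area rings are
available behind a flag for sensitivity analysis; absolute ring fractions
do depend on this choice, which is why it is surfaced.

**Density ratio.** r_fragment = median DAPI inside the territory ÷ median
DAPI over the nucleus. Medians and the ratio make the measure invariant to
channel rescaling, cancelling illumination and acquisition-time effects.

**Axial orientation.** θ is the angle between the undirected major-axis
line and the vector from the nuclear centroid to the territory centroid,
folded to [0°, 180°). Territories with θ ≤ 45° or θ ≥ 135° (both
boundaries inclusive) are major-parallel. Per-cell classes: for diploid
("normal") cells with exactly two homologs, both-minor vs one-plus-major;
for tumor cells, at-least-half-major vs under-half-major, with nuclei
dichotomised by fragmentation score (number of detected signals; ≤2 vs
>2). Nuclei with no detected territory carry no axial measurement and are
logged as excluded.

## Null models and tests

A territory "positioned at random" can mean several things; three nulls
are computed side by side:

* **naive** — p_major = 0.5 (uniform angle; exact for any shape);
* **ellipse-corrected** — a point uniform in an ellipse with semi-axes
  a ≥ b is major-parallel with probability (2/π)·arctan(a/b), the
  elliptical-sector area in closed form via the parametric-angle
  substitution. This corrects for the larger area subtended near the long
  axis; for the myoblast-scale ratio 12.8/8.7 it gives 0.620;
* **empirical-mask** — Monte-Carlo over the actual mask pixels, for
  irregular nuclei.

Observed-vs-expected counts use the exact binomial test with two-sided
p-values by the minimum-likelihood method (sum of all outcome
probabilities not exceeding the observed one, with a 1e−7 relative tie
tolerance), the convention of the commercial software whose results the
pipeline is meant to reproduce; proportions between groups use Fisher's
exact test with the same two-sided definition; measurement comparisons use
Welch's t-test. Per-cell expected proportions assume the two homologs are
positioned independently. No multiple-testing correction is applied by
default (matching the unadjusted pairwise reporting convention); Holm is
available behind a flag.

A consequence of exactness worth knowing: at n = 100 and p0 = 0.5 the
exact binomial test's attainable size at α = 0.05 is 3.5%, not 5% — the
rejection region jumps from k ≤ 39/k ≥ 61. Calibration checks of the
pipeline against a nominal 4–6% band will therefore read low; that is the
test being conservative, not a defect in the angle sampler.

## The synthetic generator

Scenes are elliptical nuclei with a radial DAPI gradient
I(ρ) = base + (peak − base)·ρ^exponent (defaults 150 → 240, exponent 1,
emulating the ~1.6× centre-to-rim rise of peripheral heterochromatin
staining), plus disc-shaped paint territories whose centroids are sampled
with ρ from a named radial law (default Beta(5, 2), peripherally
weighted) and axial angle from a von Mises distribution on the doubled
angle — an axis-symmetric family with a single concentration parameter
that is exactly uniform at concentration 0. The concentration needed for
any target major-parallel fraction is solved numerically
(`axial_concentration_for()`).

Rendering adds a fixed-magnitude (15%) planar illumination tilt in a
random direction and intensity-scaled Gaussian noise (SD 12 counts at
intensity 100, scaling as sqrt(I) — the Gaussian approximation to photon
shot noise). Both choices are realism the thresholding recipe genuinely
needs: a perfectly flat, noise-free background is a histogram delta with
zero entropy, a degenerate case the maximum-entropy criterion handles
badly and real acquisitions never produce.

Study-condition presets fix the remaining parameters:
`study_cohort_spec("myoblast_like")` renders 12.8 × 8.7 µm nuclei
(eccentricity 0.73) with two territories at 5.9% occupancy, density
contrast 1.05 and uniform angles; `"myotube_like"` renders 15.5 × 7.9 µm
nuclei (eccentricity 0.86) at 9.5% occupancy, contrast 1.16 and a true
major-parallel fraction of 0.75. Axes jitter ±8% across nuclei; pixel
size defaults to 0.12 µm/px so nuclei stay comfortably under the
10,000-px retention ceiling.

What the generator does **not** emulate: optical point-spread blur,
chromatin texture inside nuclei and territories, irregular (non-elliptic)
nuclear outlines, and z-structure. Passing recovery tests on these scenes
therefore validates the measurement chain's geometry and statistics, not
its robustness to every property of real micrographs.

```{r example, eval = FALSE}
cfg <- list(
  simulate = list(
    mt = study_cohort_spec("myotube_like", n_scenes = 10, nuclei_per_scene = 5)),
  out_dir = "demo_run", seed = 42, scheme = "tumor")
res <- run_pipeline(cfg)
res$stats
plot_radial_profile(res$nuclei)
```

## Numerical choices and degenerate inputs

* Thresholding a constant image raises a degenerate-histogram error rather
  than guessing.
* Integer-valued images are binned at unit width for the threshold; real
  valued images fall back to 256 equal-width bins.
* Ring binning is half-open with ρ = 0 in ring 1; boundary pixels land in
  ring 6; a mask too small to populate all rings is flagged, not dropped
  silently.
* Zero paint signal flags the radial profile undefined; a zero nuclear
  DAPI median makes the density ratio an error.
* Coincident territory and nuclear centroids flag the axial angle
  undefined and exclude the territory from axial statistics.
* Territory placement uses bounded rejection (200 attempts) for
  separation; exhaustion is an explicit infeasible-placement error.
* All measurement tables are written at full float precision so re-reads
  are bit-identical; derived per-scene seeds stay below 2^31.

## Problem sizes in the test suite

The verification suite runs cohorts of 50 nuclei (10 scenes × 5 nuclei)
per condition, 100 axial measurements each — the per-chromosome sample
size of the original comparisons — with 20 seeded replicates per condition
for the power/size check, and 10^6-point Monte-Carlo for the ellipse-null
cross-check. These sizes make every check reproducible on a laptop core in
minutes while keeping binomial standard errors small enough for the stated
tolerances.

## Known limitations

* The nuclear threshold sits just above the background noise floor (a
  property of maximum-entropy thresholding), so masks carry a sub-pixel
  halo; ring-6 DAPI means would be biased low if the radial gradient were
  much shallower than the defaults.
* Merged adjacent nuclei are measured as one object, inflating axis
  lengths; the original analysis accepts the same limitation.
* The ellipse-corrected null assumes territory centroids uniform over an
  ellipse; strongly non-elliptical nuclei should use the empirical-mask
  null.
* The "normal" per-cell scheme requires exactly two detected homologs and
  errors otherwise by design.
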