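# chromterr

Quantitative analysis of chromosome-territory organization in fluorescence
images of cell nuclei.

Chromosome paints label the discrete territory a chromosome occupies in an
interphase nucleus. Whether that territory sits centrally or peripherally,
how much of the nucleus it occupies, how dense its DNA is, and whether it
aligns with the nuclear major axis are all readouts of higher-order genome
organization that change with cell state — for example between
proliferating myoblasts, differentiated myotubes, and rhabdomyosarcoma
tumor cells. chromterr turns two-channel confocal stacks (DAPI + paint)
into those numbers and tests them against random-positioning null models.
It is written for image-analysis and genome-organization researchers who
want the full measurement chain as inspectable, tested R functions.

## What it computes

* **Segmentation** — nuclei from the DAPI channel (non-local-means
  normalisation → Kapur maximum-entropy threshold → radius-2 closing →
  size/border filters) and paint territories (radius-2 median filter →
  Kapur threshold confined to nuclear signal → area filter 100–10,000 px),
  with every exclusion logged.
* **Morphometry** — moment-equivalent ellipse axes, area, eccentricity
  `sqrt(1 - (minor/major)^2)`, orientation; fragmentation score (territory
  count per nucleus, dichotomised ≤2 vs >2).
* **Radial occupancy** — six concentric rings of equal normalised
  distance-to-edge (ring 1 central, ring 6 peripheral); per-ring paint
  fractions and DAPI intensities.
* **DNA density** — `r_fragment` = median territory DAPI / median nuclear
  DAPI.
* **Axial orientation** — angle θ between the nuclear major-axis line and
  the territory centroid vector; major-parallel iff θ ≤ 45° or θ ≥ 135°;
  per-cell classification for diploid and fragmented/aneuploid schemes.
* **Statistics** — exact binomial tests of observed vs expected counts
  (minimum-likelihood two-sided p), Fisher's exact test, Welch's t; null
  major-parallel probability as 0.5 (uniform angle), the closed form
  `(2/pi) * atan(a/b)` for a point uniform in an ellipse, or Monte-Carlo
  over the actual mask.
* **Synthetic scenes** — a generator producing TIFF cohorts with exact
  ground truth (nucleus geometry, territory radial position, axial angle,
  DAPI contrast), used to verify every stage.

## A worked example

```r
library(chromterr)

cfg <- list(
  simulate = list(
    myotube_like  = study_cohort_spec("myotube_like",  n_scenes = 10, nuclei_per_scene = 5),
    myoblast_like = study_cohort_spec("myoblast_like", n_scenes = 10, nuclei_per_scene = 5)),
  out_dir = "demo_run", seed = 42, scheme = "tumor")

res <- run_pipeline(cfg)
dplyr::filter(res$stats, level == "per_chromosome", null_model == "naive")
```

```
#>           group          level stratum null_model p_major_null   n n_major observed_fraction   p_value
#> 1 myoblast_like per_chromosome     all      naive          0.5 100      46              0.46 4.841e-01
#> 2  myotube_like per_chromosome     all      naive          0.5 100      77              0.77 5.514e-08
```

The myotube-like cohort (generated with a true major-parallel fraction of
0.75) shows a significant preference for the major axis against the
uniform null (77/100 territories, exact binomial p ≈ 5.5e-8), while the
myoblast-like cohort (uniform angles) does not (46/100, p ≈ 0.48). The
per-nucleus table `res$nuclei` carries axes (mean major axis ≈ 15.6 µm for
the myotube-like condition vs ≈ 12.9 µm for the myoblast-like one),
eccentricity, occupancy, ring fractions and per-cell classes;
`res$territories` carries per-territory θ, axial class and `r_fragment`.
`plot_radial_profile(res$nuclei)` and
`plot_axial_classes(res$territories, p_major_null = 0.5)` draw the standard
summaries.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/chromterr-cli.R` (subcommands `simulate` and `run`, with
`--config`, `--seed`, `--out-dir`).

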