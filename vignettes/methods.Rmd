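---
title: "Methods: image-based tiller angle phenotyping and dynamic QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based tiller angle phenotyping and dynamic QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tillerqtl` re-implements, as a tested and reusable pipeline, an image-based
phenotyping workflow for rice plant architecture together with the dynamic
QTL analysis it feeds. The tiller angle — the maximum angle between the
outermost tillers of a plant, in degrees — shapes canopy light capture,
planting density and ultimately yield; it behaves as a quantitative trait
under multi-genic control, with well-known loci on chromosomes 1, 2 and 9
(including the *TAC1* region). Because the original greenhouse imagery and
MGRIL genotypes are not deposited, every stage of this package is exercised
against a synthetic plant-image renderer and a simulated recombinant inbred
line (RIL) population in which the ground truth is known by construction.
This vignette records the models, the tunable parameters, and the design
choices made where the methods were genuinely open.

## The synthetic plant renderer

A plant is modelled as a fan of straight tillers radiating from a basal
point above a pot band on a uniform background (`plant_spec()`,
`render_plant()`). Straightness is deliberate: with straight strokes the
ground-truth angle is exactly `max(angle_i) - min(angle_i)`, so the
renderer can serve as an oracle for the measurement chain. Real tillers
curve; a curved renderer would trade an exact oracle for realism without
changing what the tests can demonstrate.

Default geometry emulates a greenhouse imaging cabinet at roughly
1 mm/pixel: a 1024 x 1024 px frame, tillers 570-630 px long and 8 px wide
(culm plus leaf sheath, about 8 mm), basal point at (512, 853) above a
147 px pot band. Two features matter for fidelity testing:

* **Basal sheath bundle.** Real tillers stay appressed inside a common
  leaf-sheath bundle near the crown and fan out above it; the basal region
  of a segmented rice mask is solid tissue, not a set of one-pixel-wide
  wedges. The renderer therefore fills the wedge between the outermost
  tillers up to `sheath_fraction` (default 0.18) of the mean tiller
  length. Without it, a fan converging on a literal point presents
  degenerate acute gaps that no smoothing filter could preserve.
* **Tiller spacing.** Interior tiller angles follow jittered equal spacing
  rather than independent uniform draws: culms occupy space, so two
  tillers cannot lie in the same plane. Independent draws occasionally
  place tillers a fraction of a degree apart, which is not physical.

Yellowing (senescing) tillers are recolored and drawn with their basal
quarter omitted, so they form connected components detached from the green
canopy — emulating dying leaves that separate from the plant, and giving
the yellow-removal stage a per-component ground truth.

Rendering is bit-deterministic given a seed; all randomness in the package
flows through explicit `seed` arguments and never touches global state.

What the renderer does **not** emulate: leaf curvature and drooping blades,
specular highlights and shadows, soil texture, overlapping neighbour
plants, and 3-D perspective. Passing the imaging tests therefore shows that
the chain is correct for clean side-view geometry, not that it is robust to
every greenhouse artifact.

## Segmentation

`segment_plant()` follows the classical color-threshold pipeline: a pixel
is tentatively plant iff its CIE L\*a\*b\* a\* and b\* values and its HSI
hue fall inside configured intervals; the binary raster is then cleaned
with a 9 x 9 median filter, repaired by morphological closing (disc radius
2) then opening (radius 1) plus hole filling, and components below
`min_component_px` are dropped. Decisions worth recording:

* The median filter acts on the binary raster after thresholding — its
  role is cleanup of the binarized image; on 0/1 data the median of an odd
  window is the exact majority vote, computed here with an integral image
  and replicate padding (so constant rasters are fixed points).
* Threshold intervals are **calibration constants, not science**: the
  defaults (`a* in [-80, 8]`, `b* in [15.5, 120]`, `H in [35, 170]` deg)
  place the decision boundary at the channel midpoints between the
  renderer's tissue palette and its background/pot, i.e. at ~50% pixel
  coverage. Any other camera or palette needs recalibration. Thresholds
  are fixed per run; per-image adaptive thresholding is left as future
  work.
* Hue is compared circularly; the interval may wrap past 360 degrees.
* An all-background scene returns an empty mask flagged with
  `empty_warning`, not an error, so batch runs survive failed pots.
* Segmentation is idempotent only up to morphological fill: pixels added
  by the median/closing steps carry background color, so re-segmenting a
  masked image reproduces the mask up to those fills (Jaccard > 0.97 in
  the test suite), a limitation inherent to any fill-then-threshold loop.

`remove_yellow_leaves()` works per connected component (leaves are removed
as units, avoiding speckled masks): a component is dropped when its mean
b\* exceeds `yellow_b_threshold` (default 45) *and* its mean a\* is >= 0,
i.e. the component is yellow-dominant rather than green.

## Shape descriptors

Six descriptors summarize the silhouette (`morphometrics()`): projected
area, convex hull area, compactness, eccentricity, and the bounding-box
extents. Two definitions were under-specified and fixed as follows:

* **Convex hull area** treats pixels as unit squares and reports the
  shoelace area of the hull polygon over pixel corners. This makes
  hull >= area an exact identity, gives a single pixel hull area 1, and
  gives the plus-sign pentomino the hand-derived value 7 (its 3 x 3
  bounding square minus four half-pixel corner triangles).
* **Compactness** is projected area over hull area — the common phenomics
  convention — so any convex filled shape scores exactly 1, and spreading
  plants score lower.
* **Eccentricity** is the conic-section eccentricity of the ellipse
  matching the second central moments of the pixel cloud,
  `sqrt(1 - lambda_min / lambda_max)` with `lambda` the eigenvalues of the
  moment matrix: 0 for a disc, 1 for a line, and `sqrt(1 - (b/a)^2)` for a
  filled ellipse with semi-axes `a >= b`. Narrow upright plants are
  near-linear (e close to 1); spreading plants become rounder, which is
  why eccentricity is the strongest negative correlate of tiller angle.

## Tiller angle measurement

`measure_tiller_angle()` chains segmentation, yellow removal, a basal crop,
vertex assignment, and a two-sided arctangent:

1. `crop_basal_region()` keeps plant pixels within `height_fraction`
   (default 1/3) of the bounding-box height above the lowest plant row.
   The crop must be tall enough to contain the tiller divergence and short
   enough to exclude drooping leaf tips; 1/3 satisfies both for the
   renderer and is configurable.
2. `find_vertices()` takes `a`/`b` as the leftmost/rightmost plant pixels
   on the top occupied row of the crop and `c`/`d` on the bottom row. The
   base point is the midpoint of `c` and `d` — the "vertices" reading, and
   more robust to asymmetric foliage than a centroid.
3. `compute_angle()` returns
   `atan(|a_x - base_x| / (base_y - a_y)) + atan(|b_x - base_x| / (base_y - b_y))`
   in degrees: the internal angle at the base subtended by the outermost
   upper vertices. Whether the original four-coordinate construction means
   a quadrilateral or two triangles cannot be read from its description;
   the two-sided atan sum is the declared interpretation here.

The measurement is a 2-D projection of a 3-D structure; per plant and
stage the package averages the available camera views (mean by default,
max via `view_aggregate`). On the renderer the method carries a small
positive bias (about +1 to +2 degrees) because the outermost *pixel* of a
stroke sits half a stroke-width outside its centerline; this is inherent
to the vertex definition and stays well within the +/- 3 degree validation
band.

## RIL simulation and genotype probabilities

The simulated population mirrors the Milyang23 x Giho design: 162 fully
inbred lines (F25+, no residual heterozygosity), 466 markers on 12
chromosomes totalling 1697 cM. The real marker spacing is unpublished, so
the synthetic map uses equal spacing — a flagged simplification, not an
assertion about the real map. Genotypes per chromosome follow a two-state
Markov chain: map distances convert to meiotic recombination through the
inverse **Kosambi** function (`r = tanh(d/50) / 2`), and meiotic `r`
expands to the line-level recombination `R = 2r / (1 + 2r)`
(Haldane-Waddington) because selfing lets recombinants accumulate over
generations. Phenotypes are
`y = mu_stage + sum_q a_q x_q + N(0, sigma_stage^2)` with `x = +1` for the
Milyang23 allele; planted QTLs are simulated on the same Markov chain as
the markers, so marker-QTL linkage is exact, and
`additive_effect_for_pve()` converts a target variance share into an
effect size (`a = sigma * sqrt(pve / (1 - pve))`).

`genotype_probabilities()` computes `P(A)` for every line on a 1 cM grid
by forward-backward smoothing on the same chain, marginalizing missing
marker calls exactly (a two-marker enumeration oracle checks this to
1e-10).

## Composite interval mapping

The scan is Haley-Knott regression: at each grid position the phenotype is
regressed on the expected genotype code `2 P(A) - 1` plus the active
cofactors, and `LOD = (n/2) log10(RSS_cofactors / RSS_full)`. Cofactors
within `window` (default 10 cM) of the test position on the same
chromosome are excluded from the model. The additive effect is the
regression coefficient on the coded genotype (half the fitted contrast
between homozygote classes; positive means the Milyang23 allele increases
the trait), and PVE is the partial R-squared at the position against total
phenotypic variance. Haley-Knott was chosen over EM interval mapping for
speed — a 200-1000-permutation threshold re-scans the genome per
permutation, which the residual-projection formulation here does as one
matrix product per cofactor configuration. Printed PVEs from other
software come from different internal estimators and need not match any
partial R-squared exactly.

Cofactors come from forward stepwise selection (`select_cofactors()`,
QTL-Cartographer-like defaults: at most 5, window 10 cM, grid 1 cM — none
of these documented for the original analysis, all configurable). Because
each step examines the best of several hundred correlated candidate
markers, the nominal entry p-value of the best candidate is essentially
always small; the entry test is therefore Bonferroni-adjusted over the
remaining candidates with threshold 0.05. Under a null trait this admits
a cofactor in well under 10% of runs, matching the intent that noise
phenotypes receive 0-1 cofactors, while a strong QTL is still picked up
immediately.

Significance uses either the fixed LOD 3.0 convention or (default) a
permutation threshold: trait values are permuted across lines, each
permutation is scanned genome-wide with the same cofactors, and the
threshold is the empirical 95th percentile of the genome-wide maximum
LOD. Both modes exist because the source analysis states both; the
package surfaces the choice rather than resolving it. Type-I calibration
of the full pipeline (selection + scan + permutation threshold) is itself
a test: across null simulations the genome-wide false-positive rate must
stay near the nominal 5% (the selection step inflates it mildly — runs
that admit a spurious cofactor are the ones that also exceed their
threshold — which is a known property of CIM, not a defect of the
implementation).

**Dynamic mapping.** Unconditional scans use the per-stage trait values
(4W-9W). Conditional scans use the exact between-stage increments
`dT_k = T(stage_k) - T(stage_{k-1})` (`conditional_phenotypes()`), with
`dT1` defined as the first-stage value itself. The increment definition is
implemented literally; mixed-model variants of conditional genetics are
out of scope.

**Peaks.** `call_peaks()` reports local maxima above threshold; the
support interval is the contiguous 1-LOD drop around the peak, bounded
outward by flanking markers (the confidence-interval convention here;
the original figures state no rule). A further peak on the same
chromosome must be at least 20 cM from an accepted interval *and* have a
genuine valley — a dip of at least 2 LOD below it — between itself and
every accepted peak; without the valley rule the slowly decaying linkage
shoulder of one strong QTL would be reported as a second locus. Peaks are
numbered `-1`, `-2` by position; names follow the `q` + trait code + chromosome + `_stage`
convention (`qTA9_5W`, conditional peaks prefixed `cq`). A conditional
peak is a **consensus** QTL when its interval shares at least 1 cM with an
unconditional interval of the same trait; overlaps with other traits'
QTLs are recorded (with the sign relation of the additive effects) but do
not confer consensus.

## Descriptive statistics

`correlation_matrix()` computes pairwise-complete Pearson correlations
with two-sided p-values on line-level means (replicates and views are
averaged before correlating). `parental_ttest()` defaults to Welch's
test, with the pooled Student variant available. Quartiles use R's
default linear-interpolation convention (type 7) — stated because
quartile conventions differ across software. `parental_ratio()` reports
the larger over the smaller parental value to one decimal.

## Problem sizes and numerical choices

The test suite validates angle recovery on 100 rendered plants (truth
spreads 10-60 degrees), segmentation on 200 plants (5-70 degrees), QTL
parameter recovery and conditional detection on 50 simulated crosses each
with 200-permutation thresholds, and type-I error on 100 null crosses —
sizes chosen so the full population-scale behavior is measured while the
suite stays desk-scale. Degenerate inputs have defined behavior
throughout: empty masks warn instead of erroring, single-pixel masks have
eccentricity 0 by convention, zero-variance t-tests return t = 0 / p = 1,
collinear cofactors are dropped with a warning, and `rss_full > rss_null`
floors the LOD at 0. Missing genotypes are marginalized by the HMM rather
than hard-imputed, trading a little speed for exactness on small data.

## Known limitations

* The straight-tiller renderer cannot probe errors caused by leaf
  curvature, occlusion between plants, or camera perspective; the
  published program's agreement with manual measurement (r ~ 0.88 on real
  plants) is not reproducible without the original imagery.
* The equal-spacing synthetic map ignores real marker clustering; LD
  structure at fine scale will differ from the true MGRIL map.
* PVE is a single-QTL partial R-squared; multi-QTL models and epistasis
  are out of scope, as is linkage-map construction itself (maps are
  inputs).
* Conditional and unconditional scans share the permutation machinery but
  are tested only under independent stage noise; strongly autocorrelated
  stage errors would lower the increments' effective signal.
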