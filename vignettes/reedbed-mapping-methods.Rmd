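---
title: "Mapping a rare wetland land cover from multi-temporal imagery: methods and design"
author: "reedmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a rare wetland land cover from multi-temporal imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reedmap)
```

## The problem

Reedbed — contiguous stands of Common Reed (*Phragmites australis*) — is a
wetland habitat of high conservation value that covers well under 1% of a
national land surface. Mapping it from satellite imagery is therefore a
*rare-class* classification problem: even a classifier with low per-pixel
error rates produces a map whose predicted reedbed is mostly false, because
the enormous area of spectrally similar vegetation (arable grasses above
all) dwarfs the true class. `reedmap` implements the full workflow for this
problem at desk scale — from raw multi-temporal 13-band reflectance passes
to an error-corrected extent estimate — together with a synthetic scene
generator that stands in for the satellite archive, so that every stage is
exercisable and testable without any data download.

## The model in brief

The classifier never sees single dates. Passes are grouped into calendar
seasons chosen so that reed is reliably photosynthetically active
("green") in one and senescent ("brown") in the other, and each season is
collapsed to a per-pixel, per-band **median composite**. The median plays
two roles: it suppresses transient contamination (notably cloud shadows,
which the cloud classifier cannot detect), and it removes most temporal
variance, leaving a stable seasonal signature. From each composite seven
spectral indices are computed —

* NDVI $= (B8-B4)/(B8+B4)$, SAVI $= 1.5\,(B8-B4)/(B8+B4+0.5)$,
  EVI $= 2.5\,(B8-B4)/(B8+6B4-7.5B2+1)$ — canopy greenness;
* NDWI $= (B3-B8)/(B3+B8)$ (McFeeters, water-positive) — winter flooding;
* RG $= B4/B3$, GB $= B3/B2$ — band ratios separating brown from green
  canopies;
* SB4 $= B4/\sum_{13} B$ — a brightness-standardised red band;

plus, in the two-season workflow, the inter-seasonal differences dSAVI and
dNDWI, giving 16 feature layers. Ratio-type indices are invariant to a
common multiplicative gain, which is why they are preferred over raw bands
when imagery from many dates and swaths is mixed.

Two random forests (500 trees, 3 variables per split) are trained on
points sampled from labelled polygons — 100 uniform draws per polygon,
same-pixel duplicates discarded — one forest class-balanced, one not, with
different seeds. The final probability is the **per-pixel minimum** of the
two forests. The minimum cannot raise any pixel's score, so predicted
(and false-positive) area can only shrink relative to either forest — the
fusion trades omission for commission, the right direction for a rare
class. Presence is declared above the probability threshold that maximises
Cohen's kappa; the threshold is chosen on *out-of-bag* fused
probabilities, so it is not tuned on in-bag fits.

The presence map is aggregated to hectare cells (mean presence over each
origin-aligned 10×10 block of valid pixels), terrain-masked (cover set to
0 where slope exceeds 10° or altitude exceeds 470 m, the national altitude
ceiling for reed — strict inequalities), and summed into a total extent.
Validation is design-based: hectares are stratified by predicted cover
(`p = 0`, three ascending intervals with half-open `(lo, hi]` membership),
drawn from the scene quadrant richest in predicted reedbed (mirroring
travel-cost-limited fieldwork), and within each hectare three predicted
presence and three predicted-absence 10 m cells are visited. From the
resulting confusion counts the mapped total $P$ is corrected as

$$\hat A_{\text{standard}} = \frac{P\,(1-c)}{1-o},$$

with $c$ the reedbed commission error and $o$ the omission error. An
alternative form that divides by $o$ instead of $1-o$ is also exposed
(`variant = "as_printed"`): the published headline extent for Britain is
reproduced only by this second form, and the text does not allow the
intended estimator to be identified, so both are implemented and the
choice is explicit in the API. The `standard` form is the package default
because it is the design-based area estimator ($P(1-c)$ estimates the true
positive area, and dividing by $1-o$ rescales for the missed fraction).

## The synthetic scene generator

The generator defines the study conditions for every test in the package.
It emulates exactly the structures the analysis depends on:

* **Landscape** — seeded region growing from Poisson-placed seeds produces
  contiguous, monodominant patches; reedbed defaults to 1% of the scene
  (rare-class regime; `landscapeSpec()` refuses reedbed fractions ≥ 5%),
  with water, grassland and an arable confusion class making up the rest.
* **Phenology** — each class carries one 13-band mean reflectance vector
  per season (piecewise-constant in time). Reed is green in summer and
  brown over a flooded base in winter (depressed NIR, red > green);
  grassland stays green-ish year-round; arable mimics reed in both phases
  within ~0.01–0.02 reflectance and is the designed confusion class. A
  `latitudeShift` (days/km of northing) can delay the phenology of
  northern rows. The literature gives no quantitative reedbed
  reflectances, so these archetypes are free parameters of the simulator,
  chosen once as plausible surface reflectance and not fitted to any
  observed scene.
* **Noise and error** — independent Gaussian band noise (default sd 0.02,
  truncated to [0, 1]), per-pass multiplicative gain and additive haze
  offset, integer mis-registration up to 3 pixels (margin invalidated),
  bright cloud blobs (all bands ≥ 0.6 before gain) and displaced 60%-dark
  shadows that are *absent from the cloud truth*, because the workflow's
  cloud classifier cannot see shadow — robustness to shadows must come
  from the median composite, and the tests verify exactly that.
* **Truth polygons** — class patches are vectorised and eroded by one
  pixel so training polygons sit away from class boundaries (one-pixel
  features vanish, as they should); oversized patches are tiled so no
  single polygon dominates training.

What the generator does **not** emulate: radiative transfer, orbital
geometry, spatially correlated (speckled or textured) noise, mixed pixels
at class boundaries, within-class spectral gradients, and true SAFE
product structure. Consequently a green test suite shows that the
*algorithmic chain* is correct and that the qualitative error structure
(confusion class → commission inflation) is reproduced; it does not show
that any particular accuracy level would be attained on real imagery.

## Numerical choices

* **Dark-object statistic**: the 1st percentile of valid pixels rather
  than the minimum, to resist single-pixel artefacts; percentile 0
  recovers plain minimum subtraction and is idempotent on noise-free
  input.
* **Registration**: normalised cross-correlation of band B8 (NIR, the
  strongest land contrast) over the jointly valid overlap, integer shifts
  only — sub-pixel resampling would smooth reflectance. Exhaustive search
  over the 7×7 shift grid; ties broken by smallest |dx|+|dy| then
  row-major order; a secondary with < 3% valid pixels raises a typed
  registration-failure error and the pipeline drops the pass.
* **Median**: even counts average the two central values (the ordinary
  sample median); pixels valid in no pass stay invalid, and composites
  never leave the convex hull of contributing values.
* **Kappa threshold**: candidates are midpoints of consecutive sorted
  unique probabilities plus 0 and 1; the smallest candidate attaining the
  maximum is returned, and equivalence with a 0.001-step brute-force scan
  is asserted in the tests (same kappa, same induced presence set).
* **Degenerate inputs**: zero index denominators yield invalid pixels,
  not errors; a chance-agreement-saturated kappa ($p_e = 1$) is defined
  as 0; single-class inputs to model fitting, AUC or threshold selection
  are errors; an all-identical probability vector is an error.
* **Terrain mask**: applied at hectare scale *after* aggregation
  (matching the workflow's stated order), with strict `>` comparisons so
  exactly-10° / exactly-470 m cells survive. Whether the published
  workflow zeroed probabilities or thresholded maps is ambiguous; masking
  the cover map is this package's documented choice.
* **Mosaicking**: overlap rule is the mean of valid values; min and max
  are options. (No cross-zone reprojection: all grids share one origin.)

## Problem sizes

The default fixture is a 200 × 200-pixel scene (4 km²) with six passes;
module tests use 60–150-pixel scenes, and the paired clean-vs-confusion
recovery experiment runs twenty 100 × 100 replicates per condition with
the full 500-tree forests. These sizes were chosen so the whole suite and
the acceptance script each run comfortably on a single core while leaving
every statistical contrast far from marginal.

## Known limitations

* The two forests differ by seed and balancing; the original workflow
  also perturbed training areas ("slightly different training areas"),
  for which `oobLearningCurve()`'s polygon subsets are the closest
  analogue.
* Hectare-scale presence uses cover > 0 on both sides; any non-zero
  threshold is available through `confusionFromRecords()`.
* Raster interchange uses multi-page float32 TIFF with a JSON sidecar
  (band names, per-band affine value encoding, NA sentinel) and
  GeoJSON/CSV for vectors and tables; no coordinate reference system is
  attached, as all grids live on one synthetic 10 m grid.
* The GEE-style four-season variant shares every stage implementation
  with the two-season workflow; only configuration differs (single
  unbalanced forest, √k variables per split, presence output, no
  difference features).
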