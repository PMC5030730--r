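---
title: "phasedyn: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phasedyn: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasedyn)
```

## The problem

Single-channel phase-contrast live imaging of cells with difficult
morphology — induced pluripotent stem cells (iPSCs) are the motivating
case — defeats the standard nucleus-seeded segmentation strategy: there is
no high-contrast subcellular reference point, edge contrast is poor, and the
cells clump. On top of that, hourly imaging adds a time dimension that most
downstream analyses (and most endpoint datasets one would like to integrate
with) do not have.

phasedyn addresses both problems in one workflow:

1. **Multi-scale segmentation.** Each frame is thresholded and labeled at
   several length scales in parallel, each scale with its own manual
   threshold and an equivalent-diameter band. The per-scale maps are then
   integrated: the largest object at a location wins, sub-objects are
   discarded, and the stack is fused through a contract/merge/relabel/expand
   round trip.
2. **Time-dimensionality reduction.** Per-object features are aggregated per
   well or per condition; each hour is reduced to an outlier-robust central
   statistic; a linear regression over hours reduces each feature to a
   single gradient; the gradients form a signature vector per
   (cell line, condition) whose pairwise correlations quantify similarity
   between cultures.

## Segmentation model and assumptions

The model assumes cells appear *darker* than the background, possibly with a
bright halo. After normalization to $[0,1]$ the frame is inverted, so a
pixel is foreground at scale $s$ iff $1 - I \ge \theta_s$. The defaults are
three scales:

| scale | threshold $\theta$ | diameter band (px) |
|------:|-------------------:|-------------------:|
| 1     | 0.78               | 5–20               |
| 2     | 0.75               | 21–40              |
| 3     | 0.74               | 41–65              |

Thresholds are non-increasing with scale size (larger, flatter structures
have weaker contrast) and diameter is the *equivalent diameter*
$2\sqrt{A/\pi}$ of the pixel area. Within a scale, connected components
(8-connected, so diagonal bridges do not split objects) are filtered to the
band, border-touching objects are discarded, and objects closer than the
unification distance (2 px, minimum pixel-centre Euclidean distance) are
merged. No intensity declumping is attempted inside a scale: the thresholded
input is near-binary, and clumps are *deliberately* kept as one object —
in-clump single cells cannot be resolved from intensity alone, and clump
morphology is itself a useful, line-specific phenotype.

**Scale priority.** A smaller-scale object whose pixel-overlap fraction with
the union of larger-scale objects exceeds `overlap_policy` is removed
entirely. The default policy is 0: any shared pixel discards the sub-object.
This implements "the largest object at a location wins"; a fractional policy
is available for softer behaviour.

**Contract/merge/relabel/expand.** Each surviving object is eroded by
`contraction_radius` (default 1 px, 3×3 structuring element, independently
per object; an object that would vanish is replaced by the maxima of its
distance transform, i.e. its ultimate erosion). The eroded binaries are
unioned, components of the union are relabeled, and labels are expanded back
into the pre-erosion union. Two deliberate choices here:

* *Expansion runs to completion*, not for a fixed number of steps. Digital
  disks have axis-tip pixels at Chebyshev distance 2 from their radius-1
  eroded core, so a literal one-step dilation would lose pixels; geodesic
  one-pixel dilations inside the pre-erosion union (nearest core wins, ties
  to the smaller label) make the round trip exactly conservative for
  well-separated objects, which is the property the test suite asserts on
  random layouts.
* *Resegmentation never splits one input object.* Erosion can disconnect a
  dumbbell-shaped clump at its neck; merged components that originate from
  the same input object are reunified. The contraction exists to keep
  *distinct neighbouring* objects from fusing across scales — not to cut
  clumps apart.

The final advisory diameter range (1–40) is **not** enforced by default:
discarding out-of-range merged objects would delete exactly the large clumps
the pipeline is designed to keep. A strict mode
(`enforce_final_d_range = TRUE`) honours it literally.

Everything in segmentation is deterministic: tie-breaks are raster-scan
order or smaller-label, and no RNG is used anywhere.

## Feature families

The default registry has 53 features: 17 intensity, 17 area/shape, 7
neighbour and 12 radial features, in a fixed, documented order (signature
vectors depend on it). Conventions, stated once and applied everywhere:
quantiles use linear interpolation between order statistics; standard
deviations are population SDs; angles are degrees in $[0, 180]$; units are
pixels and normalized intensity. The registry is extensible — larger
published feature sets (over a hundred features once texture and granularity
families are included) can be reached by registering more columns; the
reduction layer only cares about the registry order.

Notable definitions:

* **Perimeter** uses the corner-corrected chain-code estimator
  (Vossepoel–Smeulders weights: 0.980 per orthogonal step, 1.406 per
  diagonal step, −0.091 per direction change). The plain 1/√2 path length
  overestimates digital-disk circumference by a constant ≈4.9%, which would
  push a disk's form factor to ≈0.91; the corrected estimator keeps disk
  form factor within a few percent of 1, which is what the feature is for.
* **Moments** use the unit-square pixel model (+1/12 per-pixel variance), so
  a single pixel has a finite axis length, matching the regionprops
  convention.
* **Solidity and Feret diameters** are computed on the convex hull of pixel
  *corners* (the unit-square model again), with a 1° caliper sweep for the
  Feret extrema; a 10×10 square has solidity exactly 1.
* **Neighbour features** use the nearest-object partition of the whole frame
  (each pixel assigned to the nearest object, ties to the smaller label);
  two regions are neighbours if their partitions are 8-adjacent.
  `PercentTouching` is the percentage of an object's own boundary pixels
  (computed against everything that is not the object, other objects
  included) within 2 px of another object.
* **Radial distribution** uses the normalized coordinate
  $\hat r = d_\mathrm{edge}/(d_\mathrm{edge}+d_\mathrm{centre})$, 0 toward
  the edge and 1 at the innermost pixels, cut into 4 equal rings, with the
  radial CV taken over 8 angular wedges about the centroid. For a uniform
  disk the mean normalized fraction is exactly 1 in every ring; the
  innermost ring of small objects is discretization-limited (few pixels per
  wedge), which is why its CV is larger on small disks.

## Time reduction

For each group and feature, hour $h$ is reduced to the **outlier-excluded
interquartile mean**: one non-iterative pass removes values beyond
$k$ population SDs from the hour mean (default $k = 3$), then the mean of
the survivors within $[Q_1, Q_3]$ is taken. "Mean of the interquartile
range" admits several readings (IQR width, midhinge, interquartile mean); the
interquartile mean is the default because it is the reading that yields a
*location* statistic in feature units, which is what a trend over hours
needs; the other two are available via `mode =`.

The per-hour series is reduced by closed-form OLS on the integer hour index
(0-based); missing hours are simply absent from the fit, and groups with
fewer than `min_fit_points` (default 3) usable hours keep their summary row
with a missing gradient. The intercept is reported but not interpreted.
Logistic or polynomial trend models are deliberately out of scope: they
would be more sensitive but risk overfitting a single culture, defeating the
purpose of a generalizable signature.

Population heatmaps use dynamic bins: edges equally spaced over the group's
global min/max (so every value is covered by construction), default 50 bins,
and per-hour-row normalization to unit sum so hours with different cell
counts are comparable; per-matrix or max normalization would conflate count
changes with distribution changes, and max normalization is kept only as an
option.

Signature correlations are Pearson on raw gradient vectors by default, on
pairwise-complete features. Gradients have heterogeneous units, so a
z-scored variant (`standardize = TRUE`) is provided; raw is the default
because the correlation is computed within one condition level where the
unit mix is identical across vectors.

## What the synthetic generator emulates — and what it does not

`synthetic_plate_spec()` renders hourly frames over 24 h: cells as dark
disks (background 0.85, contrast 0.75, so inverted cell intensity 0.90
clears the strictest threshold) with a 1.5-px bright halo that thresholding
excludes, additive Gaussian noise (SD 0.01), linear area growth at a
condition-dependent rate (defaults 2/4/8 px²/h for conditions 1/5/25,
emulating faster spreading at higher matrix concentration), and optional
clumping: with a per-hour probability the closest pair of cells is moved
into contact and counts as one truth object from that hour on — a clump is
one object in the gold standard, mirroring how manual counts treat adherent
cells. Placement guarantees well-separated cells (final radii plus a minimum
gap), and every stream derives from one seed, so plates are bit-for-bit
reproducible.

The generator does **not** simulate phase-contrast optics (no shade-off or
realistic halo physics), cell division or death, cell motility, focus drift,
or illumination gradients. Passing the synthetic acceptance properties
therefore demonstrates the *algorithmic* contracts (exactness of the label
algebra, correct trend recovery, determinism) — not segmentation accuracy on
real microscopes, which depends on threshold tuning per instrument and cell
type.

Evaluation against truth uses greedy one-to-one IoU matching (deterministic;
descending IoU, ties to smaller labels). Hungarian matching would be
globally optimal but the greedy matcher is simple, deterministic and
sufficient at the IoU threshold (0.5) used.

## Numerical choices and degenerate inputs

* Tie-breaks: raster-scan order for label numbering, smaller label for
  merges and contested expansion pixels.
* Distance maps are exact Euclidean (verified against brute force in the
  tests); erosion/dilation treat off-image pixels as background.
* Degenerate histogram groups (min = max) collapse to a single bin.
* An hour whose values are all equal has SD 0 and excludes nothing
  ($|x-\mu| = 0 \le 0$).
* Empty frames yield empty label maps and 0-row object tables with intact
  headers; fewer than 2 (or 3) objects make closest-neighbour (or
  second-closest/angle) features `NA`, and missing values are propagated,
  never zero-filled.
* Object tables round-trip exactly through both backends: CSV floats are
  written with 17 significant digits; the SQLite file stores doubles
  natively.

## Problem sizes used in validation

The shipped tests run on sizes chosen to exercise every contract while
keeping the suite quick on a laptop: 100 random multi-scale frames
(220×220 px) for segmentation exactness, 100 random layouts for round-trip
conservation, 200 random blobs (≤30×30) against the brute-force shape
oracle, 100 seeds for noisy trend recovery (200 objects/hour × 24 h) and for
the within- vs between-line correlation property, and a 4-well × 24-hour
plate run twice end-to-end for bit-identical outputs. `scripts/acceptance.R`
recomputes the same quantities at slightly smaller sizes from a single
`--seed`.

## Known limitations

* Cells inside a clump are not resolved — by design.
* Thresholds are manual and instrument-specific; no automatic threshold
  selection is provided.
* The default registry is 53 features; texture, Zernike and granularity
  families are not implemented.
* Neighbour-partition computation scales with (number of objects) ×
  (frame area); very dense frames will be slow in the measurement step.
* The CLI covers single plates; there is no database server integration —
  persistence is per-run CSV/SQLite by design.
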