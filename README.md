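# phasedyn

Automated high-content analysis for single-channel phase-contrast
time-lapse plates. phasedyn is aimed at imaging groups working with cells
that defeat nucleus-seeded segmentation — induced pluripotent stem cells and
other lines with variable morphology and a tendency to clump — on
instruments that produce one gray channel per frame, hourly, per well.

It provides two things:

1. **Multi-scale segmentation.** The inverted, normalized frame is
   thresholded at several length scales in parallel (default three:
   thresholds θ = 0.78 / 0.75 / 0.74 with equivalent-diameter bands 5–20,
   21–40, 41–65 px, where equivalent diameter is 2·√(A/π)). Per-scale
   objects are filtered by diameter, unified within 2 px, integrated by
   largest-object priority (sub-objects discarded), and fused by a
   contract/merge/relabel/expand round trip into one label map per frame.
   Clumps are deliberately segmented as one object.
2. **Time-dimensionality reduction.** Each per-object feature (53 by
   default: intensity, shape, neighbour and radial families) is aggregated
   per well or per condition; every hour is reduced to the
   outlier-excluded interquartile mean (values beyond 3 population SDs of
   the hour mean dropped, then the mean of survivors within [Q1, Q3]); a
   linear regression over hours reduces the series to a gradient β (feature
   units per hour). The gradients, in registry order, form a **signature
   vector** per (cell line, condition); Pearson correlation matrices between
   signature vectors quantify similarity between cultures.

A synthetic plate generator with pixel-exact ground truth makes the whole
workflow testable without any imaging data, and a CLI
(`inst/cli/phasedyn.R`) drives `simulate → segment → measure → reduce` from
the shell.

## Worked example

```r
library(phasedyn)

spec <- synthetic_plate_spec(
  wells = data.frame(well = c("B2", "B3"), cell_line = c("L1", "L1"),
                     condition = c("1", "25")),
  shape = c(160L, 160L), cells_per_well = 4L, n_hours = 12L, seed = 7L)

fr  <- generate_frame(spec, "B2", 5)     # one frame + ground truth
lab <- segment_frame(fr$image)           # default three-scale config
max(lab)
#> [1] 4
segmentation_metrics(lab, fr$labels)[c("precision", "recall", "count_error")]
#> precision 1, recall 1, count_error 0

ot <- measure_all(lab, fr$image, meta = list(plate_id = "P1", well_id = "B2", hour = 5L))
ot[, c("object_id", "Shape_Area", "Shape_FormFactor", "Intensity_MeanIntensity")]
#>   object_id Shape_Area Shape_FormFactor Intensity_MeanIntensity
#> 1         1        114            1.174                   0.099
#> 2         2         58            1.221                   0.100
#> 3         3         60            1.283                   0.100
#> 4         4         90            1.197                   0.099

d <- tempfile()
pipeline_run(run_config(output_dir = d, spec = spec, seed = 7L))
s <- read.csv(file.path(d, "reduce", "summary_condition.csv"))
subset(s, feature_name == "Shape_Area",
       select = c(group_id, gradient, intercept, n_hours_used))
#>    group_id gradient intercept n_hours_used
#> 18     L1|1 1.774476  64.36538           12
#> 71    L1|25 8.234266  82.71154           12
```

The two `Shape_Area` gradients recover the generator's condition-dependent
area growth rates (2 and 8 px²/h for conditions 1 and 25; the small
deviation is disk rasterization). The per-object rows show four cells found
with perfect count agreement against truth; mean intensity ≈ 0.10 is the
rendered cell intensity (background 0.85 − contrast 0.75).

From the shell, the same run is:

```sh
Rscript inst/cli/phasedyn.R run --output-dir out --seed 7
```

## Repository layout

- `R/` — implementation: plate data model and persistence, segmentation,
  feature measurement, population dynamics, synthetic data, CLI commands.
- `inst/extdata/feature_registry.csv` — the default 53-feature registry.
- `inst/cli/phasedyn.R` — command-line entry point.
- `vignettes/phasedyn-methods.Rmd` — methods, parameter rationale, and
  design notes.
- `tests/testthat/` — unit, property and end-to-end acceptance tests with
  independent brute-force oracles.
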