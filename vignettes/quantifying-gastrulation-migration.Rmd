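---
title: "Quantifying mesendodermal cell migration in zebrafish gastrulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mesendodermal cell migration in zebrafish gastrulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastrutrack)
library(dplyr)
```

## The measurement problem

During zebrafish gastrulation, endodermal and mesodermal cells internalize at
the embryo margin and migrate toward the animal pole. Two kinds of raw data
quantify this behaviour: *snapshots* (in situ hybridization images of
marker-positive cells, e.g. *sox17* for endoderm and *fn1a* for mesoderm) and
*time-lapse tracks* (light-sheet movies of GFP-labelled cells, tracked
manually or with TrackMate). Neither is directly comparable across embryos:
embryos differ in size, orientation and developmental timing. `gastrutrack`
implements the normalizations and statistics that make them comparable, plus
a synthetic-embryo simulator that generates data with the same statistical
structure so every stage of the pipeline can be tested without imaging data.

## The embryo coordinate frame

Snapshot and track coordinates are expressed in a frame defined by three
annotated landmarks — the animal pole, the vegetal pole and a dorsal
reference — plus the measured embryo height and width
(`embryo_geometry()`). Positions are projected onto the animal–vegetal axis
and rescaled to **percent embryo height**: the vegetal pole maps to 0%, the
animal pole to 100% (`relative_height()`). The perpendicular distance from
the axis, divided by the embryo width, is the signed **lateral offset**
(`lateral_offset()`, positive toward dorsal). Both quantities are invariant
under rigid transforms applied jointly to landmarks and cells, so
microscope orientation cannot leak into the results.

Three numerical choices are worth stating:

* The lateral view is treated as a flat 2D plane — no spherical correction —
  because that reproduces what measurements on maximum-intensity projections
  deliver. Positions near the embryo silhouette's rim are therefore slightly
  compressed along the axis relative to arc length on the sphere; all
  genotypes are affected identically.
* Positions projecting slightly outside `[0, 100]`% are clamped within a
  tolerance (default 1% of height, reflecting landmark click error); beyond
  it they are rejected, or dropped with a warning under `clip = TRUE`.
* The center of the lateral side is the point 90° around the embryo from
  dorsal; in the lateral view it projects onto the axis, so it defaults to
  the midpoint of the pole-to-pole segment and the lateral offset reduces to
  the perpendicular distance from the axis. Whether the lateral offset
  should be a straight-line image distance or an arc length along the
  surface is not determined by the measurement procedure; straight-line
  distance is used.

## Snapshot statistics

Endodermal cell number is proxied by the count of marker-positive cells
falling on or within 10% of the embryo width from the lateral center
(`count_lateral_cells()`, closed boundary, threshold configurable). Pooled
position distributions histogram the percent height of all selected cells
across embryos (`position_distribution()`, default 5% bins — binned
proportions, not smoothed densities). Mesodermal migration is summarized per
embryo by the leading edge: the mean height of the `k` most-animal cells
(`leading_edge_height()`, default `k = 1`, since published per-embryo
scatter plots show one point per embryo). Group differences use the
unpaired two-tailed Student's t-test (`compare_groups()`; Welch behind a
flag — Student's equal-variance form is the field's historical default for
this phrase).
Cells are pooled across embryos for distributions, but statistical
comparisons are always per embryo: the embryo, not the cell, is the
independent unit.

## Trajectory statistics

Tracks from different embryos are aligned at the **onset of
internalization** (`align_at_onset()`), the biological time origin, and
binned into equal-length time windows — four 45-min windows on a 180-min
movie (`bin_into_windows()`; half-open intervals, final window closed, so
every point is assigned exactly once). Two filters guard against noise:
segments with fewer than 5 points in a window are excluded, and the entire
first window is excluded by default (tracking is unreliable while cells are
still internalizing). Both are parameters, not constants.

Per segment, four statistics are computed (`window_metrics()`):

* **path length** — summed per-frame step magnitudes (µm);
* **net displacement** — first-to-last straight-line distance (µm);
* **straightness** — net displacement / path length, in [0, 1];
* **speed** — path length / elapsed time (µm/min).

Terminology around straightness is inconsistent in this assay's
literature: "total displacement" sometimes denotes the summed path and
"total distance" the net first-to-last distance, which inverts the ratio.
The conventional [0, 1]-bounded index (net/path) is implemented because it
is the standard migration statistic and the only reading consistent with
the word *straightness* (1 = straight, 0 = closed loop); the inverted
ratio is available via `straightness(..., reciprocal = TRUE)`. "Velocity"
here is path-based speed — cumulative distance over time — not the
net-displacement rate.

Directional behaviour is summarized by a displacement-weighted **rose
histogram** (`rose_histogram()`): each per-frame step adds its magnitude to
the angular bin of its direction in the anatomical frame (dorsal = 0°,
animal = 90°, counter-clockwise by default, matching the A/D/Vg/V compass
labelling of rose plots in this field; the convention is configurable).
Default 8 bins, centered on the four cardinal
directions and the diagonals so that a step exactly animal-ward falls in
the middle of the animal bin. Zero-magnitude steps are skipped: they carry
no direction and zero weight. Weights are additive across any split of the
step set before normalization, and proportions sum to 1.

## Proliferation and death

Division (track-splitting) events are counted in consecutive observation
windows (default 20, 54 and 20 frames — the acquisition's focus-correction
blocks) and divided by the cells present at each window's start
(`proliferation_windows()`); per-embryo proliferation is the unweighted
mean over windows (`embryo_proliferation()`). Cells born from a division
mid-window enter the starting count of the next window only ("present at
the beginning" is taken literally), and one split is one event regardless
of daughter count. Deaths are summarized per embryo as count and fraction
of tracked cells (`death_summary()`); classifying deaths from images is out
of scope — deaths enter as track-termination annotations.

## The synthetic embryo

`simulate_tracks()` implements the minimal generative model whose
statistics the pipeline's metrics detect: a biased random walk in the 2D
lateral plane. Each frame a cell moves by a drift vector expressed in the
anatomical frame plus isotropic Gaussian noise; tracks split or terminate
with per-window probabilities, daughters displaced from the parent by one
extra noise step. There are no cell–cell interactions, no confinement to
the embryo outline and no epiboly surface flow: the pipeline fits no
dynamical model, so the simulator emulates only the statistical structure
the metrics assume. Passing tests on simulated data therefore demonstrate
correctness of the *measurement* pipeline, not fidelity to real embryo
mechanics: real trajectories are spatially correlated between neighbours,
confined, and have stage-dependent drift, none of which the generator
produces.

Default conditions mirror the study's acquisitions: 60 cells per embryo,
180 min (roughly 50% → 85% epiboly) at 2-min frames (≤ 3 min as in the
mesoderm movies; the endoderm proliferation setting uses 3.5-min frames
over 20/54/20-frame windows), a 700 µm embryo, cells starting at 5–25%
height within the ±10%-width lateral band. The genotype presets encode the
qualitative published contrast as fixed test conditions — wild type:
animal drift 0.4 µm/min, step noise σ = 1 µm; mutant: drift 0.1 µm/min,
σ = 0.8 µm (no numeric speeds are published; these are fixtures chosen once
to separate clearly at n = 200, not estimates). `expected_speed()` provides
the closed-form oracle for speed recovery: step magnitudes are Rice
distributed, with mean `σ√(π/2)·L½(−ν²/2σ²)` for drift ν per frame,
evaluated through exponentially scaled Bessel functions so the σ → 0 limit
is stable.

## Problem sizes and reproducibility

The test and acceptance workloads use 100 random tracks for oracle
equivalence, 200–300 cells for drift/genotype contrasts, 500 simulated
embryos for division-probability recovery and 10,000 replicates for t-test
calibration — sizes at which Monte-Carlo error is far smaller than the
effects being checked while a full run stays in the minutes range on one
core. Every stochastic step is seeded; a fixed seed reproduces simulator
output byte-for-byte, and all tolerance choices (1e-9 for oracle
equivalence, 3 Monte-Carlo standard errors for recovery checks, 2 for the
unbiasedness check) are stated where they are used.

## A worked run

```{r example}
wt <- genotype_preset("wildtype", n_cells = 100, seed = 1) |>
  simulate_tracks(genotype = "wildtype") |>
  align_at_onset()
metrics <- window_metrics(wt)
summarize_by_genotype(metrics)

pts <- bin_into_windows(wt)
rose <- rose_histogram(pts[!is.na(pts$window) & pts$window > 1, ],
                       wt$geometry)
direction_proportion(rose, "animal")
```

```{r plot, fig.width = 5, fig.height = 4}
autoplot(rose)
```

## Known limitations

* 2D lateral-view analysis only; no 3D or spherical-coordinate metrics.
* The TrackMate reader targets the stable spot/edge core of the schema;
  merges are rejected and features/filters/views ignored.
* The simulator's division/death scheduling draws at most one event per
  cell per window, so per-window probabilities above ~0.5 compress event
  timing toward window interiors.
* No mean-squared-displacement or persistence-time analysis — the pipeline
  computes exactly the published statistics.
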