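# gastrutrack

Quantification of mesendodermal cell migration in zebrafish gastrulation,
from stained snapshots and time-lapse cell tracks.

During gastrulation, endodermal (*sox17*+) and mesodermal (*fn1a*+,
*drl:eGFP*+) cells internalize at the embryo margin and migrate toward the
animal pole. Comparing this behaviour across embryos and genotypes requires
normalizing away embryo size, orientation and developmental timing.
`gastrutrack` implements that normalization and the statistics built on it,
for developmental biologists analyzing ImageJ/TrackMate measurements:

* **Embryo coordinate frame** — positions from landmark-annotated images are
  expressed as *percent embryo height* along the animal–vegetal (AP–VP)
  axis (vegetal pole = 0%, animal pole = 100%) and as a signed *lateral
  offset* in units of embryo width.
* **Snapshot analysis** — cell counts within 10% of the embryo width of the
  lateral center (a proxy for endodermal cell number), pooled
  percent-height position distributions, per-embryo leading-edge heights of
  the most animally migrated cells, and unpaired two-tailed t-tests between
  genotypes.
* **Trajectory analysis** — tracks (TrackMate-style XML or plain CSV) are
  aligned at the onset of internalization, binned into equal time windows
  (default four, e.g. 45-min windows over a 180-min movie), and filtered to
  segments with ≥ 5 points per window (the first window is excluded by
  default). Per cell and window: path length `L = Σᵢ |xᵢ₊₁ − xᵢ|`, net
  displacement `D = |x_last − x_first|`, straightness `S = D/L ∈ [0, 1]`,
  and speed `v = L/Δt` (µm/min). Directionality is summarized by
  displacement-weighted rose histograms in the anatomical frame
  (A/D/Vg/V compass).
* **Proliferation and death** — division (track-splitting) events per
  observation window divided by cells present at the window start, averaged
  per embryo; death counts and fractions from track fates.
* **Synthetic embryos** — a seeded biased-random-walk simulator
  (drift in the anatomical frame + isotropic Gaussian step noise, division
  and death events) with wild-type and mutant presets, plus a closed-form
  Rice-mean speed oracle (`expected_speed()`), so the whole pipeline is
  testable without imaging data.

## Worked example

Simulate a wild-type and a mutant embryo, run the trajectory pipeline, and
compare genotypes:

```r
library(gastrutrack)
library(dplyr)

sets <- lapply(c("wildtype", "mutant"), function(g) {
  p <- genotype_preset(g, n_cells = 100, seed = 1)
  simulate_tracks(p, embryo_id = paste0(g, "_1"), genotype = g) |>
    align_at_onset()
})

metrics <- bind_rows(lapply(sets, window_metrics))
summarize_by_genotype(metrics)
#> # A tibble: 12 × 7
#>    genotype window metric           n  mean     sem sem_defined
#>    <chr>     <int> <chr>        <int> <dbl>   <dbl> <lgl>
#>  1 mutant        2 speed          100 0.508 0.00568 TRUE
#>  2 mutant        2 straightness   100 0.261 0.0138  TRUE
#>  3 mutant        3 speed          100 0.500 0.00564 TRUE
#>  4 mutant        3 straightness   100 0.282 0.0117  TRUE
#>  5 mutant        4 speed          100 0.508 0.00554 TRUE
#>  6 mutant        4 straightness   100 0.265 0.0120  TRUE
#>  7 wildtype      2 speed          100 0.715 0.00805 TRUE
#>  8 wildtype      2 straightness   100 0.549 0.0131  TRUE
#>  9 wildtype      3 speed          100 0.713 0.00854 TRUE
#> 10 wildtype      3 straightness   100 0.568 0.0130  TRUE
#> 11 wildtype      4 speed          100 0.723 0.00677 TRUE
#> 12 wildtype      4 straightness   100 0.576 0.0107  TRUE
```

Mutant cells are slower (≈ 0.50 vs ≈ 0.72 µm/min) and less straight
(≈ 0.27 vs ≈ 0.57) in every analyzed window — the pipeline's readout of the
presets' reduced animal-directed drift and smaller steps. The same contrast
appears in the direction histograms:

```r
for (s in sets) {
  pts <- bin_into_windows(s)
  rose <- rose_histogram(pts[!is.na(pts$window) & pts$window > 1, ],
                         s$geometry)
  cat(s$genotype, "animal-bin proportion:",
      round(direction_proportion(rose, "animal"), 3), "\n")
}
#> wildtype animal-bin proportion: 0.314
#> mutant animal-bin proportion: 0.177
```

i.e. 31% of wild-type displacement is spent moving animally versus 18% in
the mutant (uniform would be 12.5% across 8 bins). `autoplot(rose)` draws
the compass-style rose plot. Snapshot records work the same way: simulated
or measured cell tables are annotated with `annotate_positions()`, counted
with `count_lateral_cells()`, and their migration front summarized with
`leading_edge_height()` — one value per embryo, compared across genotypes
with `compare_groups()`.

A command-line front end wraps the same functions for shell pipelines
(`inst/cli/gastrutrack.R`; subcommands `simulate`, `track-metrics`,
`positions`, `proliferation`; every run writes a `manifest.json` with the
resolved configuration and seed).

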