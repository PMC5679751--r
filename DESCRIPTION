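Package: gastrutrack
Title: Quantification of Mesendodermal Cell Migration in Zebrafish Gastrulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cell migration during zebrafish gastrulation
    from time-lapse tracks and stained snapshots. Positions are normalized to
    percent embryo height along the animal-vegetal axis; lateral endodermal
    cells are counted inside a 10 percent-of-embryo-width window; mesodermal
    trajectories are aligned at the onset of internalization, binned into
    equal time windows, filtered by a minimum number of points, and summarized
    as straightness, speed and displacement-weighted directional (rose)
    histograms. A synthetic-embryo simulator generates biased-random-walk
    tracks with genotype-dependent animal-pole-directed drift, division and
    death events, so every pipeline stage can be tested without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
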