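#' Select cells in the lateral analysis window
#'
#' Keeps cells falling on or within `half_width_frac` of the embryo width
#' from the center of the lateral side (default 10%, a closed boundary:
#' a cell exactly at the threshold is retained).
#'
#' @param cells A tibble with a `lateral_offset` column (see
#'   [annotate_positions()]).
#' @param half_width_frac Half-width of the window as a fraction of embryo
#'   width (default 0.10).
#' @return The retained rows (possibly none).
#' @export
select_lateral_cells <- function(cells, half_width_frac = 0.10) {
  require_columns(cells, "lateral_offset", "cell table")
  dplyr::filter(cells, abs(.data$lateral_offset) <= half_width_frac)
}

#' Count cells in the lateral window (endoderm cell-number proxy)
#'
#' The number of marker-positive cells inside the lateral window is used as
#' a proxy for endodermal cell number. Counts are per embryo when an
#' `embryo_id` column is present.
#'
#' @inheritParams select_lateral_cells
#' @return A tibble with `embryo_id` (if present) and `n_cells`.
#' @export
count_lateral_cells <- function(cells, half_width_frac = 0.10) {
  kept <- select_lateral_cells(cells, half_width_frac)
  if ("embryo_id" %in% names(cells)) {
    all_ids <- dplyr::distinct(cells, .data$embryo_id)
    kept |>
      dplyr::count(.data$embryo_id, name = "n_cells") |>
      dplyr::right_join(all_ids, by = "embryo_id") |>
      dplyr::mutate(n_cells = tidyr::replace_na(.data$n_cells, 0L)) |>
      dplyr::arrange(.data$embryo_id)
  } else {
    tibble::tibble(n_cells = nrow(kept))
  }
}

#' Distribution of cell positions along the animal-vegetal axis
#'
#' Pools the selected cells of all embryos and histograms their percent
#' embryo height into equal bins over \[0, 100\], normalized to the
#' proportion of cells per bin ("the frequency with which cells were found
#' at a given location"). Cells, not embryo averages, are pooled, matching
#' consolidation across embryos; group-level statistics are instead
#' computed per embryo.
#'
#' @param cells A tibble with a `relative_height` column; typically already
#'   restricted to the lateral window via [select_lateral_cells()].
#' @param bin_width Bin width in percent embryo height (default 5).
#' @return A tibble of class `position_distribution` with columns
#'   `bin_start`, `bin_end`, `count`, `frequency`; attribute `n_cells`.
#' @export
position_distribution <- function(cells, bin_width = 5) {
  require_columns(cells, "relative_height", "cell table")
  h <- cells$relative_height[!is.na(cells$relative_height)]
  if (!length(h)) stop("no cells to histogram", call. = FALSE)
  if (bin_width <= 0 || bin_width > 100) {
    stop("bin_width must be in (0, 100]", call. = FALSE)
  }
  edges <- unique(c(seq(0, 100, by = bin_width), 100))
  n_bins <- length(edges) - 1
  bin <- pmin(findInterval(h, edges), n_bins) # final bin closed at 100
  counts <- tabulate(bin, nbins = n_bins)
  out <- tibble::tibble(
    bin_start = edges[-length(edges)],
    bin_end = edges[-1],
    count = counts,
    frequency = counts / sum(counts)
  )
  attr(out, "n_cells") <- length(h)
  class(out) <- c("position_distribution", class(out))
  out
}

#' Leading-edge height of migrating cells, per embryo
#'
#' The percent embryo height of the most animally migrated cell(s): the
#' mean `relative_height` of the `k` most-animal cells of each embryo
#' (default `k = 1`, the single front cell). One value per embryo is the
#' migration readout entering group comparisons.
#'
#' @param cells A tibble with `relative_height` and optionally `embryo_id`.
#' @param k Number of most-animal cells averaged (default 1).
#' @return A tibble with `embryo_id` (if present) and `leading_edge`
#'   (percent embryo height).
#' @export
leading_edge_height <- function(cells, k = 1) {
  require_columns(cells, "relative_height", "cell table")
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  top_mean <- function(h) {
    h <- h[!is.na(h)]
    if (length(h) < k) {
      stop("fewer than k = ", k, " cells in an embryo", call. = FALSE)
    }
    mean(sort(h, decreasing = TRUE)[seq_len(k)])
  }
  if ("embryo_id" %in% names(cells)) {
    cells |>
      dplyr::group_by(.data$embryo_id) |>
      dplyr::summarise(leading_edge = top_mean(.data$relative_height),
                       .groups = "drop")
  } else {
    tibble::tibble(leading_edge = top_mean(cells$relative_height))
  }
}

#' Unpaired two-tailed t-test between two groups of per-embryo values
#'
#' The group comparison used throughout the study's figures: an unpaired
#' two-tailed Student's t-test (equal variances). Welch's unequal-variance
#' test is available behind a flag.
#'
#' @param values_a,values_b Numeric vectors of per-embryo measurements,
#'   each with at least 2 values.
#' @param welch Use Welch's test instead of Student's (default `FALSE`).
#' @return A one-row tibble: `n_a`, `n_b`, `mean_a`, `mean_b`, `t`, `df`,
#'   `p`.
#' @export
compare_groups <- function(values_a, values_b, welch = FALSE) {
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (sd(values_a) == 0 && sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    # identical constant groups: no evidence of difference
    return(tibble::tibble(
      n_a = length(values_a), n_b = length(values_b),
      mean_a = mean(values_a), mean_b = mean(values_b),
      t = 0, df = length(values_a) + length(values_b) - 2, p = 1
    ))
  }
  if (sd(c(values_a - mean(values_a), values_b - mean(values_b))) == 0) {
    stop("degenerate (zero) pooled variance; t-test undefined", call. = FALSE)
  }
  ht <- stats::t.test(values_a, values_b, var.equal = !welch,
                      alternative = "two.sided")
  tibble::tibble(
    n_a = length(values_a), n_b = length(values_b),
    mean_a = mean(values_a), mean_b = mean(values_b),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value
  )
}

#' Pairwise group comparison table
#'
#' Runs [compare_groups()] for every requested pair of groups in a
#' per-embryo value table, e.g. leading-edge heights or lateral cell counts
#' by genotype.
#'
#' @param df A tibble with a grouping column and a value column.
#' @param group,value Column names (strings) of group labels and values.
#' @param reference If non-`NULL`, compare every other group against this
#'   one (as the figures compare each genotype with wild type); otherwise
#'   all pairs.
#' @param welch Passed to [compare_groups()].
#' @return A tibble with `group_a`, `group_b` and the [compare_groups()]
#'   columns.
#' @export
compare_group_table <- function(df, group = "genotype", value = "value",
                                reference = NULL, welch = FALSE) {
  require_columns(df, c(group, value), "comparison input")
  labels <- unique(df[[group]])
  pairs <- if (!is.null(reference)) {
    if (!reference %in% labels) {
      stop("reference group '", reference, "' not present", call. = FALSE)
    }
    lapply(setdiff(labels, reference), function(g) c(reference, g))
  } else {
    utils::combn(labels, 2, simplify = FALSE)
  }
  purrr::map_dfr(pairs, function(pr) {
    va <- df[[value]][df[[group]] == pr[1]]
    vb <- df[[value]][df[[group]] == pr[2]]
    dplyr::bind_cols(
      tibble::tibble(group_a = pr[1], group_b = pr[2]),
      compare_groups(va, vb, welch = welch)
    )
  })
}
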