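#' Align a track set at the onset of internalization
#'
#' Shifts all timestamps so that the embryo's internalization onset becomes
#' time 0. Aligning each embryo at its own onset makes time windows
#' comparable across embryos whose acquisitions started at different
#' developmental moments. Points recorded before onset are retained with
#' negative times (they fall outside all analysis windows).
#'
#' @param ts A [track_set()] with `internalization_onset` set.
#' @return The track set with shifted times and `internalization_onset = 0`.
#' @export
align_at_onset <- function(ts) {
  stopifnot(is_track_set(ts))
  onset <- ts$internalization_onset
  if (is.na(onset)) {
    stop("internalization_onset is unset; cannot align", call. = FALSE)
  }
  if (nrow(ts$tracks) && onset > max(ts$tracks$t)) {
    stop("internalization onset is later than the last timestamp of every ",
         "track; nothing analyzable", call. = FALSE)
  }
  ts$tracks$t <- ts$tracks$t - onset
  ts$internalization_onset <- 0
  ts
}

is_aligned <- function(ts) {
  !is.na(ts$internalization_onset) && ts$internalization_onset == 0
}

#' Window boundaries of the observation span
#'
#' The observation span `[0, T]` (from onset to the last timestamp present)
#' is split into `n_windows` equal-length windows. Windows are half-open
#' `[start, end)`; the final window is closed at `T`, so every point in the
#' span is assigned exactly once.
#'
#' @param ts An aligned [track_set()].
#' @param n_windows Number of equal windows (default 4, giving 45-min
#'   windows on a 180-min span).
#' @return Numeric vector of `n_windows + 1` boundaries in minutes.
#' @export
window_boundaries <- function(ts, n_windows = 4) {
  stopifnot(is_track_set(ts))
  if (n_windows < 1) stop("n_windows must be >= 1", call. = FALSE)
  if (!is_aligned(ts)) {
    stop("track set is not aligned at internalization onset; ",
         "call align_at_onset() first", call. = FALSE)
  }
  tt <- ts$tracks$t[ts$tracks$t >= 0]
  if (!length(tt) || max(tt) <= 0) {
    stop("no observation span after onset", call. = FALSE)
  }
  seq(0, max(tt), length.out = n_windows + 1)
}

#' Assign track points to equal time windows
#'
#' Bins each point of an aligned track set into one of `n_windows`
#' equal-length windows spanning onset to the last timestamp ("binned based
#' on real time"). Pre-onset points (negative times) get window `NA`.
#'
#' @inheritParams window_boundaries
#' @return A tibble of the track points with an integer `window` column
#'   (1-based) and the boundaries in the `"boundaries"` attribute.
#' @export
bin_into_windows <- function(ts, n_windows = 4) {
  edges <- window_boundaries(ts, n_windows)
  wlen <- diff(edges)[1]
  pts <- ts$tracks
  w <- ifelse(pts$t < 0, NA_integer_,
              pmin(floor(pts$t / wlen) + 1L, n_windows))
  pts$window <- as.integer(w)
  attr(pts, "boundaries") <- edges
  pts
}

points_matrix <- function(points) {
  require_columns(points, c("x", "y"), "point table")
  cbind(points$x, points$y)
}

#' Per-segment trajectory metrics
#'
#' The four per-cell-per-window migration statistics:
#' * `path_length()`: summed per-frame Euclidean step magnitudes (µm) -- the
#'   cumulative distance actually travelled;
#' * `net_displacement()`: straight-line distance between the first and last
#'   point (µm);
#' * `straightness()`: `net_displacement / path_length`, a dimensionless
#'   index in \[0, 1\] -- 1 for straight constant-direction motion, 0 for a
#'   closed loop. Set `reciprocal = TRUE` for the inverted ratio
#'   (path / net, >= 1);
#' * `speed()`: `path_length` divided by elapsed time (µm/min).
#'
#' @param points A data frame with columns `x`, `y` (and `t` for `speed()`),
#'   ordered by time; at least 2 rows.
#' @return A single number. `straightness()` returns `NA` when the cell never
#'   moved (`path_length == 0`): the index is undefined and such segments are
#'   excluded from aggregates.
#' @export
path_length <- function(points) {
  xy <- points_matrix(points)
  if (nrow(xy) < 2) stop("need at least 2 points", call. = FALSE)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' @rdname path_length
#' @export
net_displacement <- function(points) {
  xy <- points_matrix(points)
  if (nrow(xy) < 2) stop("need at least 2 points", call. = FALSE)
  sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
}

#' @param reciprocal If `TRUE`, return `path_length / net_displacement`
#'   instead of the bounded index.
#' @rdname path_length
#' @export
straightness <- function(points, reciprocal = FALSE) {
  pl <- path_length(points)
  nd <- net_displacement(points)
  if (pl == 0) return(NA_real_)
  if (reciprocal) {
    if (nd == 0) return(NA_real_)
    pl / nd
  } else {
    nd / pl
  }
}

#' @rdname path_length
#' @export
speed <- function(points) {
  require_columns(points, "t", "point table")
  if (nrow(points) < 2) stop("need at least 2 points", call. = FALSE)
  dt <- points$t[nrow(points)] - points$t[1]
  if (dt <= 0) stop("zero elapsed time in segment", call. = FALSE)
  path_length(points) / dt
}

#' Per-cell, per-window migration metrics for a track set
#'
#' Aligns nothing and filters everything: the track set must already be
#' aligned (see [align_at_onset()]). Each track's points are binned into
#' `n_windows` equal windows; each track-window segment with at least
#' `min_points` points yields path length, net displacement, straightness
#' and speed. Segments below the point threshold, and all of window 1 when
#' `exclude_first` (the default, matching the study's exclusion of the first
#' window from analysis), are kept in the table but flagged `included =
#' FALSE` so they stay out of aggregate statistics.
#'
#' @inheritParams window_boundaries
#' @param min_points Minimum points per window for a segment to enter
#'   statistics (default 5).
#' @param exclude_first Exclude window 1 from aggregates (default `TRUE`).
#' @return A tibble with columns `embryo_id`, `genotype`, `track_id`,
#'   `window`, `n_points`, `path_length`, `net_displacement`,
#'   `straightness`, `speed`, `included`.
#' @export
window_metrics <- function(ts, n_windows = 4, min_points = 5,
                           exclude_first = TRUE) {
  pts <- bin_into_windows(ts, n_windows)
  pts <- pts[!is.na(pts$window), , drop = FALSE]
  out <- pts |>
    dplyr::arrange(.data$track_id, .data$t) |>
    dplyr::group_by(.data$track_id, .data$window) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      path_length = if (dplyr::n() >= 2)
        path_length(dplyr::pick("x", "y")) else NA_real_,
      net_displacement = if (dplyr::n() >= 2)
        net_displacement(dplyr::pick("x", "y")) else NA_real_,
      straightness = if (dplyr::n() >= 2)
        straightness(dplyr::pick("x", "y")) else NA_real_,
      speed = if (dplyr::n() >= 2)
        speed(dplyr::pick("t", "x", "y")) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      included = .data$n_points >= min_points &
        !(exclude_first & .data$window == 1L),
      embryo_id = ts$embryo_id,
      genotype = ts$genotype,
      .before = 1
    ) |>
    dplyr::relocate("embryo_id", "genotype", "track_id")
  out
}

#' Group means of straightness and speed by genotype and window
#'
#' Summarizes per-cell window metrics (possibly pooled over several embryos
#' with [dplyr::bind_rows()]) into per-genotype, per-window mean, SEM and
#' cell count for straightness and speed. Only rows flagged `included` and
#' with a defined value enter; a group with a single cell reports `sem = 0`
#' with `sem_defined = FALSE`.
#'
#' @param metrics A tibble from [window_metrics()] (rows from several
#'   embryos may be concatenated).
#' @return A tibble with columns `genotype`, `window`, `metric`
#'   (`"straightness"` or `"speed"`), `n`, `mean`, `sem`, `sem_defined`.
#' @export
summarize_by_genotype <- function(metrics) {
  require_columns(metrics, c("genotype", "window", "straightness", "speed",
                             "included"), "metrics table")
  long <- metrics |>
    dplyr::filter(.data$included) |>
    tidyr::pivot_longer(c("straightness", "speed"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  if (!nrow(long)) {
    warning("no included metric values to summarize", call. = FALSE)
  }
  long |>
    dplyr::group_by(.data$genotype, .data$window, .data$metric) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sem = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else 0,
      sem_defined = dplyr::n() > 1,
      .groups = "drop"
    )
}
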