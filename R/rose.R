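#' Displacement-weighted directional (rose) histogram
#'
#' For every consecutive per-frame step of every qualifying track segment,
#' the step's magnitude is added to the angular bin of its anatomical
#' movement direction; bin weights are then normalized to proportions. Each
#' bin therefore represents the proportion of movement in that direction
#' weighted by the distance travelled in it. Zero-magnitude steps carry no
#' direction and no weight and are skipped.
#'
#' With the default 8 bins, bins are centered on the four cardinal
#' anatomical directions and the diagonals (`center_on_axes = TRUE`), so a
#' step exactly animal-ward falls in the middle of the "animal" bin.
#'
#' @param points A tibble of track points with columns `track_id`, `t`,
#'   `x`, `y`, and optionally `window` (as from [bin_into_windows()]); when
#'   `window` is present, the minimum-point filter and step pairing are
#'   applied per track-window segment.
#' @param geom An [embryo_geometry()].
#' @param conv A [direction_convention()].
#' @param n_bins Number of angular bins (default 8).
#' @param min_points Minimum points per segment (default 5).
#' @param center_on_axes Center bins on the cardinal directions (default
#'   `TRUE`); otherwise bins start at angle 0.
#' @return A tibble of class `rose_histogram` with columns `bin`,
#'   `bin_start`, `bin_end` (degrees, in the convention's frame), `weight`
#'   (summed step magnitudes, µm) and `proportion`; attributes `n_cells`
#'   (contributing cells) and `convention`.
#' @export
rose_histogram <- function(points, geom, conv = direction_convention(),
                           n_bins = 8, min_points = 5,
                           center_on_axes = TRUE) {
  stopifnot(is_embryo_geometry(geom))
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  steps <- segment_steps(points, min_points = min_points)
  steps <- steps[steps$mag > 0, , drop = FALSE]
  if (!nrow(steps) || sum(steps$mag) <= 0) {
    stop("no positive-magnitude steps in any qualifying segment; ",
         "rose histogram undefined", call. = FALSE)
  }
  ang <- movement_angle(steps$dx, steps$dy, geom, conv)
  w <- 360 / n_bins
  offset <- if (center_on_axes) w / 2 else 0
  bin <- (floor((ang + offset) / w) %% n_bins) + 1L
  weight <- vapply(seq_len(n_bins),
                   function(b) sum(steps$mag[bin == b]), numeric(1))
  centers <- (seq_len(n_bins) - 1L) * w
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    bin_start = (centers - offset) %% 360,
    bin_end = centers - offset + w,
    weight = weight,
    proportion = weight / sum(weight)
  )
  attr(out, "n_cells") <- dplyr::n_distinct(steps$track_id)
  attr(out, "convention") <- conv
  class(out) <- c("rose_histogram", class(out))
  out
}

# consecutive within-segment steps of qualifying segments
segment_steps <- function(points, min_points = 5) {
  require_columns(points, c("track_id", "t", "x", "y"), "point table")
  points <- tibble::as_tibble(points)
  if (!"window" %in% names(points)) points$window <- 1L
  points <- points[!is.na(points$window), , drop = FALSE]
  points |>
    dplyr::arrange(.data$track_id, .data$t) |>
    dplyr::group_by(.data$track_id, .data$window) |>
    dplyr::filter(dplyr::n() >= min_points) |>
    dplyr::reframe(
      t = .data$t[-1],
      dx = diff(.data$x),
      dy = diff(.data$y),
      mag = sqrt(diff(.data$x)^2 + diff(.data$y)^2)
    )
}

#' @export
print.rose_histogram <- function(x, ...) {
  cat(sprintf("<rose_histogram> %d bins, %d cells\n",
              nrow(x), attr(x, "n_cells") %||% NA_integer_))
  NextMethod()
}

#' Proportion of movement toward one anatomical direction
#'
#' Looks up the rose-histogram bin whose center is the given cardinal
#' direction under the histogram's angle convention and returns its
#' proportion -- e.g. the animal-bin proportion used to quantify
#' animal-pole-directed migration.
#'
#' @param rose A [rose_histogram()].
#' @param direction One of `"animal"`, `"dorsal"`, `"vegetal"`, `"ventral"`.
#' @return The bin's proportion (a single number).
#' @export
direction_proportion <- function(rose, direction = "animal") {
  stopifnot(inherits(rose, "rose_histogram"))
  conv <- attr(rose, "convention") %||% direction_convention()
  direction <- match.arg(direction, c("animal", "dorsal", "vegetal", "ventral"))
  ang <- conv$labels[[direction]]
  hit <- which(((ang - rose$bin_start) %% 360) <
                 (rose$bin_end - rose$bin_start))
  if (!length(hit)) stop("no bin contains direction ", direction, call. = FALSE)
  rose$proportion[hit[1]]
}

#' Rose histograms per time window
#'
#' Convenience wrapper computing one displacement-weighted rose histogram
#' for each analysis window of an aligned track set (window 1 excluded by
#' default, as in the windowed trajectory statistics).
#'
#' @inheritParams window_metrics
#' @inheritParams rose_histogram
#' @return A tibble of stacked rose rows with a leading `window` column.
#' @export
window_roses <- function(ts, geom = NULL, conv = direction_convention(),
                         n_windows = 4, n_bins = 8, min_points = 5,
                         exclude_first = TRUE, center_on_axes = TRUE) {
  geom <- geom %||% ts$geometry
  if (is.null(geom)) stop("no embryo geometry available", call. = FALSE)
  pts <- bin_into_windows(ts, n_windows)
  windows <- seq_len(n_windows)
  if (exclude_first) windows <- windows[-1]
  purrr::map_dfr(windows, function(w) {
    sub <- pts[!is.na(pts$window) & pts$window == w, , drop = FALSE]
    rose <- tryCatch(
      rose_histogram(sub, geom, conv, n_bins = n_bins,
                     min_points = min_points,
                     center_on_axes = center_on_axes),
      error = function(e) {
        warning("window ", w, ": ", conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (is.null(rose)) return(NULL)
    dplyr::mutate(tibble::as_tibble(rose), window = w, .before = 1)
  })
}
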