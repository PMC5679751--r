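#' Proliferation rate within one observation window
#'
#' Percent proliferation: the number of division (track-splitting) events in
#' a window divided by the number of cells present at the beginning of that
#' window, times 100.
#'
#' @param n_divisions,n_cells_at_start Non-negative counts (vectorized).
#' @return Percent proliferation.
#' @export
proliferation_rate <- function(n_divisions, n_cells_at_start) {
  if (any(n_cells_at_start <= 0)) {
    stop("n_cells_at_start must be > 0", call. = FALSE)
  }
  if (any(n_divisions < 0)) stop("n_divisions must be >= 0", call. = FALSE)
  100 * n_divisions / n_cells_at_start
}

#' Observation-window division and death counts for one embryo
#'
#' Splits the observation period into consecutive windows of the given frame
#' spans (default 20, 54 and 20 frames, the acquisition's three
#' focus-correction blocks) and counts, per window, the cells present at the
#' window start, the division events and the death events. A cell is present
#' at a window start if its track spans that time; cells born from a
#' division mid-window are counted from the next window on. One division is
#' one splitting event regardless of daughter count.
#'
#' @param ts A [track_set()]; track fates encode divisions and deaths.
#' @param frame_spans Integer vector of frames per window (default
#'   `c(20, 54, 20)`).
#' @return A tibble with one row per window: `window`, `n_frames`,
#'   `t_start`, `t_end`, `n_cells_at_start`, `n_divisions`, `n_deaths`,
#'   `rate` (percent proliferation).
#' @export
proliferation_windows <- function(ts, frame_spans = c(20, 54, 20)) {
  stopifnot(is_track_set(ts))
  if (any(frame_spans < 1)) stop("frame_spans must be >= 1", call. = FALSE)
  per <- track_summary(ts)
  if (!nrow(per)) stop("track set has no tracks", call. = FALSE)
  t0 <- min(per$first_t)
  edges <- t0 + cumsum(c(0, frame_spans)) * ts$frame_interval
  n_win <- length(frame_spans)
  purrr::map_dfr(seq_len(n_win), function(w) {
    s <- edges[w]; e <- edges[w + 1]
    present <- per$first_t <= s & per$last_t > s
    div <- per$fate == "divided" & per$last_t >= s & per$last_t < e
    die <- per$fate == "died" & per$last_t >= s & per$last_t < e
    if (w == n_win) { # final window closed at its end
      div <- per$fate == "divided" & per$last_t >= s & per$last_t <= e
      die <- per$fate == "died" & per$last_t >= s & per$last_t <= e
    }
    n0 <- sum(present)
    tibble::tibble(
      window = w, n_frames = frame_spans[w], t_start = s, t_end = e,
      n_cells_at_start = n0, n_divisions = sum(div), n_deaths = sum(die),
      rate = if (n0 > 0) proliferation_rate(sum(div), n0) else NA_real_
    )
  })
}

#' Per-embryo proliferation: mean over the observation windows
#'
#' Averages the per-window percent-proliferation rates over all observation
#' windows of one embryo (unweighted, as the windows are analysis blocks of
#' the same cohort).
#'
#' @param wins A tibble from [proliferation_windows()], or a numeric vector
#'   of per-window rates.
#' @param n_windows Expected number of windows (default 3); a mismatch is an
#'   error.
#' @return Percent proliferation (a single number).
#' @export
embryo_proliferation <- function(wins, n_windows = 3) {
  rates <- if (is.data.frame(wins)) {
    require_columns(wins, "rate", "window table")
    wins$rate
  } else {
    as.numeric(wins)
  }
  if (length(rates) != n_windows) {
    stop("expected ", n_windows, " observation windows, got ", length(rates),
         call. = FALSE)
  }
  mean(rates)
}

#' Per-embryo death count and fraction
#'
#' Counts tracks whose fate is `"died"` and expresses them as a fraction of
#' all tracked cells -- the track-level summary supporting comparisons of
#' cell-death rates between genotypes.
#'
#' @param ts A [track_set()].
#' @return A one-row tibble: `embryo_id`, `genotype`, `n_tracks`,
#'   `n_deaths`, `fraction`.
#' @export
death_summary <- function(ts) {
  stopifnot(is_track_set(ts))
  per <- track_summary(ts)
  n <- nrow(per)
  d <- sum(per$fate == "died")
  tibble::tibble(
    embryo_id = ts$embryo_id, genotype = ts$genotype,
    n_tracks = n, n_deaths = d,
    fraction = if (n > 0) d / n else 0
  )
}
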