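#' Simulation parameters for a synthetic gastrulating embryo
#'
#' Configures the biased-random-walk model of ventrolateral mesendodermal
#' cell migration in the 2D lateral plane: each frame a cell moves by a
#' deterministic drift expressed in the anatomical frame (animal, dorsal,
#' vegetal components, µm/min) plus isotropic Gaussian noise (`noise_sigma`
#' µm per step). Tracks may split (division) or terminate (death) with
#' per-window probabilities. Defaults describe a wild-type embryo imaged
#' over 180 min (roughly 50% to 85% epiboly) at 2-min frame intervals, with
#' cells starting in a band just above the margin on the lateral side.
#'
#' @param n_cells Number of starting cells (default 60).
#' @param duration Total imaged time in minutes (default 180).
#' @param frame_interval Minutes between frames (default 2).
#' @param drift_animal,drift_dorsal,drift_vegetal Drift components in
#'   µm/min along the anatomical axes (defaults 0.4, 0, 0: animal-directed
#'   wild-type drift).
#' @param noise_sigma Isotropic Gaussian step noise, µm per step
#'   (default 1).
#' @param division_prob_per_window,death_prob_per_window Per-cell
#'   probabilities of dividing/dying within one event window (defaults 0).
#' @param n_event_windows Number of equal-length event windows (default 4);
#'   ignored when `event_frame_spans` is given.
#' @param event_frame_spans Optional integer vector of frames per event
#'   window (e.g. `c(20, 54, 20)`), overriding the equal split.
#' @param height,width Embryo dimensions in µm (defaults 700 x 700, a
#'   gastrula-stage zebrafish embryo).
#' @param start_height_band Percent-height band in which cells start
#'   (default `c(5, 25)`, just above the vegetal margin).
#' @param start_half_width_frac Half-width of the starting lateral band as
#'   a fraction of embryo width (default 0.10).
#' @param time_origin Clock time (minutes) of the first frame; recorded as
#'   the internalization onset (default 0).
#' @param seed Optional integer seed; a given seed reproduces the track set
#'   exactly.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_cells = 60, duration = 180, frame_interval = 2,
                       drift_animal = 0.4, drift_dorsal = 0,
                       drift_vegetal = 0, noise_sigma = 1,
                       division_prob_per_window = 0,
                       death_prob_per_window = 0,
                       n_event_windows = 4, event_frame_spans = NULL,
                       height = 700, width = 700,
                       start_height_band = c(5, 25),
                       start_half_width_frac = 0.10,
                       time_origin = 0, seed = NULL) {
  p <- list(
    n_cells = n_cells, duration = duration, frame_interval = frame_interval,
    drift_animal = drift_animal, drift_dorsal = drift_dorsal,
    drift_vegetal = drift_vegetal, noise_sigma = noise_sigma,
    division_prob_per_window = division_prob_per_window,
    death_prob_per_window = death_prob_per_window,
    n_event_windows = n_event_windows,
    event_frame_spans = event_frame_spans,
    height = height, width = width,
    start_height_band = start_height_band,
    start_half_width_frac = start_half_width_frac,
    time_origin = time_origin, seed = seed
  )
  rates <- c(drift_animal, drift_dorsal, drift_vegetal, noise_sigma,
             division_prob_per_window, death_prob_per_window)
  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  if (duration < frame_interval) {
    stop("duration must be >= frame_interval", call. = FALSE)
  }
  if (n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
  if (division_prob_per_window + death_prob_per_window > 1) {
    stop("division + death probability per window must be <= 1", call. = FALSE)
  }
  if (height <= 0 || width <= 0) stop("height and width must be > 0",
                                      call. = FALSE)
  if (length(start_height_band) != 2 ||
      any(start_height_band < 0 | start_height_band > 100) ||
      diff(start_height_band) < 0) {
    stop("start_height_band must be an increasing pair in [0, 100]",
         call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' Genotype presets for the simulator
#'
#' Fixed parameter sets emulating the study's genotype contrast: mutant
#' cells have strictly lower animal-directed drift (diminished
#' animal-pole-directed migration) and smaller noise steps (slower cells)
#' than wild type. Further arguments override preset fields.
#'
#' @param label `"wildtype"` or `"mutant"`.
#' @param ... Overrides passed to [sim_params()].
#' @return A [sim_params()] object.
#' @export
genotype_preset <- function(label = c("wildtype", "mutant"), ...) {
  label <- match.arg(label)
  defaults <- switch(label,
    wildtype = list(drift_animal = 0.4, noise_sigma = 1),
    mutant = list(drift_animal = 0.1, noise_sigma = 0.8)
  )
  over <- list(...)
  do.call(sim_params, utils::modifyList(defaults, over))
}

#' Default lateral-view embryo geometry used by the simulator
#'
#' Vegetal pole at the origin, animal pole straight up, dorsal to the right.
#'
#' @param height,width Embryo dimensions in µm.
#' @return An [embryo_geometry()].
#' @export
default_geometry <- function(height = 700, width = 700) {
  embryo_geometry(
    animal = c(0, height), vegetal = c(0, 0),
    dorsal = c(width / 2, height / 2),
    width = width, height = height
  )
}

sim_event_edges <- function(p) {
  n_frames <- round(p$duration / p$frame_interval)
  spans <- p$event_frame_spans
  if (is.null(spans)) {
    edges <- round(seq(0, n_frames, length.out = p$n_event_windows + 1))
  } else {
    if (sum(spans) > n_frames) {
      stop("event_frame_spans exceed the simulated frame count", call. = FALSE)
    }
    edges <- cumsum(c(0, spans))
  }
  if ((p$division_prob_per_window > 0 || p$death_prob_per_window > 0) &&
      any(diff(edges) < 2)) {
    stop("event windows must span at least 2 frames when division or death ",
         "probabilities are non-zero", call. = FALSE)
  }
  list(n_frames = n_frames, edges = edges)
}

#' Simulate a tracked embryo
#'
#' Runs the drift-plus-noise walk of [sim_params()]: cells start near the
#' margin in the lateral band, step each frame by the anatomical drift
#' vector plus isotropic Gaussian noise, and may divide (the track splits
#' into two daughters, each displaced from the parent by one extra noise
#' step) or die (the track terminates) at a random frame inside each event
#' window. Output is fully reproducible from the seed.
#'
#' @param p A [sim_params()] object.
#' @param embryo_id,genotype Labels stored in the result.
#' @return A [track_set()] whose geometry is [default_geometry()] of the
#'   configured dimensions and whose `internalization_onset` equals the
#'   simulation's time origin.
#' @export
simulate_tracks <- function(p, embryo_id = "sim1", genotype = "wildtype") {
  stopifnot(inherits(p, "sim_params"))
  if (!is.null(p$seed)) set.seed(p$seed)
  geom <- default_geometry(p$height, p$width)
  dt <- p$frame_interval
  ev <- sim_event_edges(p)
  n_frames <- ev$n_frames
  edges <- ev$edges

  drift_xy <- dt * ((p$drift_animal - p$drift_vegetal) * geom$axis_animal +
                      p$drift_dorsal * geom$axis_dorsal)

  empty_set <- function() {
    track_set(
      tibble::tibble(track_id = character(), t = numeric(), x = numeric(),
                     y = numeric(), parent_id = character(),
                     fate = character()),
      geometry = geom, embryo_id = embryo_id, genotype = genotype,
      internalization_onset = p$time_origin, frame_interval = dt
    )
  }
  if (p$n_cells == 0) return(empty_set())

  n0 <- p$n_cells
  cap <- max(16L, n0 * 8L)
  X <- matrix(NA_real_, n_frames + 1L, cap)
  Y <- matrix(NA_real_, n_frames + 1L, cap)
  birth <- rep(NA_integer_, cap)
  last <- rep(NA_integer_, cap)
  fate <- rep(NA_character_, cap)
  parent <- rep(NA_character_, cap)
  ev_type <- rep(0L, cap)   # 0 none, 1 divide, 2 die
  ev_frame <- rep(NA_integer_, cap)

  grow <- function(need) {
    while (need > ncol(X)) {
      add <- ncol(X)
      X <<- cbind(X, matrix(NA_real_, n_frames + 1L, add))
      Y <<- cbind(Y, matrix(NA_real_, n_frames + 1L, add))
      birth <<- c(birth, rep(NA_integer_, add))
      last <<- c(last, rep(NA_integer_, add))
      fate <<- c(fate, rep(NA_character_, add))
      parent <<- c(parent, rep(NA_character_, add))
      ev_type <<- c(ev_type, rep(0L, add))
      ev_frame <<- c(ev_frame, rep(NA_integer_, add))
    }
  }

  # starting positions: percent-height band on the lateral side
  rh <- runif(n0, p$start_height_band[1], p$start_height_band[2]) / 100
  off <- runif(n0, -p$start_half_width_frac, p$start_half_width_frac) * p$width
  X[1, seq_len(n0)] <- geom$vegetal[1] + rh * (geom$animal[1] - geom$vegetal[1]) +
    off * geom$axis_dorsal[1]
  Y[1, seq_len(n0)] <- geom$vegetal[2] + rh * (geom$animal[2] - geom$vegetal[2]) +
    off * geom$axis_dorsal[2]
  birth[seq_len(n0)] <- 0L
  fate[seq_len(n0)] <- "alive"
  n_tracks <- n0
  active <- seq_len(n0)

  schedule <- function(w) {
    s <- edges[w]; e <- edges[w + 1]
    eligible <- active[birth[active] <= s]
    if (!length(eligible)) return(invisible())
    u <- runif(length(eligible))
    pd <- p$division_prob_per_window
    pq <- p$death_prob_per_window
    typ <- ifelse(u < pd, 1L, ifelse(u < pd + pq, 2L, 0L))
    interior <- seq.int(s + 1L, max(s + 1L, e - 1L))
    frames <- interior[1L + floor(runif(length(eligible)) * length(interior))]
    ev_type[eligible] <<- typ
    ev_frame[eligible] <<- ifelse(typ > 0L, frames, NA_integer_)
  }

  win <- 1L
  schedule(1L)
  for (f in seq_len(n_frames)) {
    if (win < length(edges) - 1L && f == edges[win + 1L]) {
      win <- win + 1L
      schedule(win)
    }
    na <- length(active)
    if (na) {
      noise <- matrix(rnorm(2L * na, sd = p$noise_sigma), na, 2L)
      X[f + 1L, active] <- X[f, active] + drift_xy[1] + noise[, 1]
      Y[f + 1L, active] <- Y[f, active] + drift_xy[2] + noise[, 2]
      due <- active[!is.na(ev_frame[active]) & ev_frame[active] == f]
      for (j in due) {
        if (ev_type[j] == 2L) { # death: track ends here
          last[j] <- f
          fate[j] <- "died"
          active <- setdiff(active, j)
        } else {               # division: split into two daughters
          last[j] <- f
          fate[j] <- "divided"
          active <- setdiff(active, j)
          grow(n_tracks + 2L)
          for (k in 1:2) {
            d <- n_tracks + k
            pert <- rnorm(2L, sd = p$noise_sigma)
            X[f + 1L, d] <- X[f + 1L, j] + pert[1]
            Y[f + 1L, d] <- Y[f + 1L, j] + pert[2]
            birth[d] <- f
            fate[d] <- "alive"
            parent[d] <- as.character(j)
          }
          active <- c(active, n_tracks + 1:2)
          n_tracks <- n_tracks + 2L
        }
      }
    }
  }
  last[active] <- n_frames

  ids <- as.character(seq_len(n_tracks))
  rows <- vector("list", n_tracks)
  for (j in seq_len(n_tracks)) {
    fr <- seq.int(birth[j], last[j])
    rows[[j]] <- tibble::tibble(
      track_id = ids[j],
      t = p$time_origin + fr * dt,
      x = X[fr + 1L, j], y = Y[fr + 1L, j],
      parent_id = parent[j], fate = fate[j]
    )
  }
  track_set(dplyr::bind_rows(rows), geometry = geom, embryo_id = embryo_id,
            genotype = genotype, internalization_onset = p$time_origin,
            frame_interval = dt)
}

#' Simulate a stained-snapshot cell record
#'
#' Positions of the simulated cells at one developmental time, converted to
#' percent-height/lateral-offset records as a stand-in for in situ
#' hybridization position data. Cells drifting outside the embryo outline
#' are clipped with a warning.
#'
#' @param p A [sim_params()] object.
#' @param stage_time Minutes after the time origin (must be within the
#'   simulated duration).
#' @param marker Marker label stored in the record (default `"sox17"`).
#' @inheritParams simulate_tracks
#' @return A tibble with columns `embryo_id`, `genotype`, `marker`, `x`,
#'   `y`, `relative_height`, `lateral_offset`; the geometry is attached as
#'   the `"geometry"` attribute.
#' @export
simulate_snapshot <- function(p, stage_time, marker = "sox17",
                              embryo_id = "sim1", genotype = "wildtype") {
  stopifnot(inherits(p, "sim_params"))
  if (stage_time < 0 || stage_time > p$duration) {
    stop("stage_time must be within [0, duration]", call. = FALSE)
  }
  ts <- simulate_tracks(p, embryo_id = embryo_id, genotype = genotype)
  geom <- ts$geometry
  tq <- p$time_origin + round(stage_time / p$frame_interval) * p$frame_interval
  per <- track_summary(ts)
  cells <- ts$tracks |>
    dplyr::semi_join(
      per[per$first_t <= tq & per$last_t >= tq, "track_id", drop = FALSE],
      by = "track_id"
    ) |>
    dplyr::filter(.data$t == tq) |>
    dplyr::distinct(.data$track_id, .keep_all = TRUE) |>
    dplyr::transmute(
      embryo_id = embryo_id, genotype = genotype, marker = marker,
      .data$x, .data$y
    )
  out <- annotate_positions(cells, geom, clip = TRUE)
  attr(out, "geometry") <- geom
  out
}

#' Closed-form expected cell speed under the simulation model
#'
#' Analytic mean per-step displacement magnitude divided by the frame
#' interval. A step is drift plus isotropic 2D Gaussian noise, so its
#' magnitude follows a Rice distribution with location `|drift| *
#' frame_interval` and scale `noise_sigma`; the mean is
#' `sigma * sqrt(pi/2) * L_{1/2}(-nu^2 / (2 sigma^2))` (the Laguerre
#' function evaluated via scaled Bessel functions). Used as the independent
#' oracle for speed recovery from the pipeline.
#'
#' @param p A [sim_params()] object.
#' @return Expected speed in µm/min.
#' @export
expected_speed <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  d <- sqrt((p$drift_animal - p$drift_vegetal)^2 + p$drift_dorsal^2)
  nu <- d * p$frame_interval
  sigma <- p$noise_sigma
  rice_mean(nu, sigma) / p$frame_interval
}

rice_mean <- function(nu, sigma) {
  if (sigma == 0) return(nu)
  x <- nu^2 / (2 * sigma^2)
  # exp(-x/2) folded into the exponentially scaled Bessel functions
  sigma * sqrt(pi / 2) *
    ((1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
       x * besselI(x / 2, 1, expon.scaled = TRUE))
}
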