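# Shared fixtures and independent naive oracles.
# The oracles recompute every statistic with plain loops directly from raw
# (t, x, y) rows, sharing no code with the package internals.

upright_geom <- function(height = 100, width = 100) {
  embryo_geometry(
    animal = c(0, height), vegetal = c(0, 0),
    dorsal = c(width / 2, height / 2), width = width, height = height
  )
}

# rigid transform: rotate by theta (radians) then translate
rigid_xy <- function(x, y, theta, shift) {
  cbind(
    cos(theta) * x - sin(theta) * y + shift[1],
    sin(theta) * x + cos(theta) * y + shift[2]
  )
}

rigid_geom <- function(geom, theta, shift) {
  tr <- function(p) as.numeric(rigid_xy(p[1], p[2], theta, shift))
  embryo_geometry(
    animal = tr(geom$animal), vegetal = tr(geom$vegetal),
    dorsal = tr(geom$dorsal), width = geom$width, height = geom$height,
    lateral_center = tr(geom$lateral_center)
  )
}

# --- naive metric oracles (loops over raw rows) ------------------------------

naive_path_length <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }
  s
}

naive_net_displacement <- function(x, y) {
  n <- length(x)
  sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
}

naive_straightness <- function(x, y) {
  naive_net_displacement(x, y) / naive_path_length(x, y)
}

naive_speed <- function(t, x, y) {
  naive_path_length(x, y) / (t[length(t)] - t[1])
}

# naive rose weights: per step, anatomical angle from first principles,
# linear scan over bins with wrap-around
naive_rose_weights <- function(x, y, geom, n_bins = 8) {
  w <- 360 / n_bins
  starts <- ((seq_len(n_bins) - 1) * w - w / 2) %% 360
  weights <- numeric(n_bins)
  for (i in seq_len(length(x) - 1)) {
    dx <- x[i + 1] - x[i]
    dy <- y[i + 1] - y[i]
    mag <- sqrt(dx^2 + dy^2)
    if (mag == 0) next
    a <- dx * geom$axis_animal[1] + dy * geom$axis_animal[2]
    d <- dx * geom$axis_dorsal[1] + dy * geom$axis_dorsal[2]
    ang <- (atan2(a, d) * 180 / pi) %% 360
    for (b in seq_len(n_bins)) {
      if (((ang - starts[b]) %% 360) < w) {
        weights[b] <- weights[b] + mag
        break
      }
    }
  }
  weights
}

# random free-diffusion-plus-drift track, built without the simulator
random_track_points <- function(n_points, drift = c(0, 0), sigma = 1,
                                dt = 2, origin = c(0, 50)) {
  steps_x <- rnorm(n_points - 1, drift[1] * dt, sigma)
  steps_y <- rnorm(n_points - 1, drift[2] * dt, sigma)
  tibble::tibble(
    t = (seq_len(n_points) - 1) * dt,
    x = origin[1] + c(0, cumsum(steps_x)),
    y = origin[2] + c(0, cumsum(steps_y))
  )
}

# --- TrackMate-style XML fixture builder -------------------------------------

# spots: data.frame id, frame, x, y (optionally z); edges: data.frame
# track, source, target
write_trackmate_fixture <- function(path, spots, edges,
                                    timeinterval = 2, version = "7.11.1") {
  spot_lines <- vapply(seq_len(nrow(spots)), function(i) {
    z <- if ("z" %in% names(spots)) sprintf(' POSITION_Z="%g"', spots$z[i]) else ""
    sprintf('      <Spot ID="%s" FRAME="%d" POSITION_X="%g" POSITION_Y="%g"%s/>',
            spots$id[i], spots$frame[i], spots$x[i], spots$y[i], z)
  }, character(1))
  track_lines <- character()
  if (nrow(edges)) {
    for (tid in unique(edges$track)) {
      e <- edges[edges$track == tid, ]
      track_lines <- c(
        track_lines,
        sprintf('    <Track TRACK_ID="%s">', tid),
        sprintf('      <Edge SPOT_SOURCE_ID="%s" SPOT_TARGET_ID="%s"/>',
                e$source, e$target),
        "    </Track>"
      )
    }
  }
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<TrackMate version="%s">', version),
    "  <Settings>",
    sprintf('    <ImageData timeinterval="%g" spatialunits="micron"/>',
            timeinterval),
    "  </Settings>",
    "  <Model>",
    "    <AllSpots>",
    '      <SpotsInFrame frame="0">',
    spot_lines,
    "      </SpotsInFrame>",
    "    </AllSpots>",
    "    <AllTracks>",
    track_lines,
    "    </AllTracks>",
    "  </Model>",
    "</TrackMate>"
  ), path)
  path
}

# the seven-offset lateral-window toy set
toy_offsets <- c(0, 0.02, 0.05, 0.10, 0.11, 0.20, 0.50)

toy_cells <- function(geom = upright_geom()) {
  # cells at axis midheight, displaced dorsally by the toy offsets
  tibble::tibble(
    embryo_id = "e1",
    x = toy_offsets * geom$width,
    y = geom$height / 2
  ) |>
    annotate_positions(geom)
}

# straight three-step track fixture used across IO tests
two_track_spots <- function() {
  data.frame(
    id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    frame = c(0, 1, 2, 0, 1, 2),
    x = c(0, 1, 2, 10, 11, 12),
    y = c(0, 0, 0, 5, 5, 5)
  )
}

two_track_edges <- function() {
  data.frame(
    track = c("0", "0", "1", "1"),
    source = c("a1", "a2", "b1", "b2"),
    target = c("a2", "a3", "b2", "b3")
  )
}
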