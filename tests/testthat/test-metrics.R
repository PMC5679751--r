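simple_ts <- function(tracks, onset = NA_real_, frame_interval = 2) {
  track_set(tracks, geometry = upright_geom(), embryo_id = "e1",
            internalization_onset = onset, frame_interval = frame_interval)
}

test_that("alignment shifts all timestamps so onset is zero", {
  ts <- simple_ts(tibble::tibble(track_id = "1", t = c(30, 75), x = 0:1, y = 0),
                  onset = 30)
  al <- align_at_onset(ts)
  expect_equal(al$tracks$t, c(0, 45))
  expect_equal(al$internalization_onset, 0)
  # two embryos with different onsets align their t = 0 frames at onset
  ts2 <- simple_ts(tibble::tibble(track_id = "1", t = c(50, 60), x = 0:1, y = 0),
                   onset = 50)
  expect_equal(align_at_onset(ts2)$tracks$t[1], 0)
  # pre-onset points kept with negative times
  ts3 <- simple_ts(tibble::tibble(track_id = "1", t = c(10, 30, 50),
                                  x = 0:2, y = 0), onset = 30)
  expect_equal(align_at_onset(ts3)$tracks$t, c(-20, 0, 20))
})

test_that("alignment errors on unset or unanalyzable onsets", {
  ts <- simple_ts(tibble::tibble(track_id = "1", t = c(0, 2), x = 0:1, y = 0))
  expect_error(align_at_onset(ts), "unset")
  late <- simple_ts(tibble::tibble(track_id = "1", t = c(0, 2), x = 0:1, y = 0),
                    onset = 100)
  expect_error(align_at_onset(late), "nothing analyzable")
})

test_that("equal windows cover the span half-open with the last closed", {
  tr <- tibble::tibble(track_id = "1", t = seq(0, 180, by = 3),
                       x = seq_along(seq(0, 180, by = 3)), y = 0)
  ts <- align_at_onset(simple_ts(tr, onset = 0))
  expect_equal(window_boundaries(ts, 4), c(0, 45, 90, 135, 180))
  pts <- bin_into_windows(ts, 4)
  expect_equal(pts$window[pts$t == 45], 2L)   # boundary point: next window
  expect_equal(pts$window[pts$t == 44 | pts$t == 42][1], 1L)
  expect_equal(pts$window[pts$t == 180], 4L)  # final boundary stays in-window
  expect_true(all(!is.na(pts$window)))
  expect_error(window_boundaries(ts, 0), "n_windows")
  # pre-onset points fall outside all windows
  tr2 <- tibble::tibble(track_id = "1", t = c(-10, 0, 90), x = 1:3, y = 0)
  ts2 <- simple_ts(tr2, onset = 0)
  expect_true(is.na(bin_into_windows(ts2, 2)$window[1]))
})

test_that("path, net displacement, straightness and speed match hand values", {
  right_angle <- tibble::tibble(t = c(0, 1, 2), x = c(0, 1, 1), y = c(0, 0, 1))
  expect_equal(path_length(right_angle), 2)
  expect_equal(net_displacement(right_angle), sqrt(2))
  expect_equal(straightness(right_angle), sqrt(2) / 2)

  straight <- tibble::tibble(t = c(0, 5), x = c(0, 10), y = 0)
  expect_equal(path_length(straight), net_displacement(straight))
  expect_equal(straightness(straight), 1)
  expect_equal(speed(straight), 2)

  loop <- tibble::tibble(t = 0:4, x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
  expect_equal(net_displacement(loop), 0)
  expect_equal(straightness(loop), 0)

  zigzag <- tibble::tibble(t = c(0, 5, 10), x = c(0, 10, 0), y = 0)
  expect_equal(speed(zigzag), 2) # path-based: 20 um over 10 min

  still <- tibble::tibble(t = c(0, 10), x = 1, y = 1)
  expect_equal(path_length(still), 0)
  expect_equal(speed(still), 0)
  expect_true(is.na(straightness(still)))
  expect_equal(straightness(right_angle, reciprocal = TRUE), 2 / sqrt(2))

  expect_error(path_length(tibble::tibble(x = 1, y = 1)), "2 points")
  expect_error(speed(tibble::tibble(t = c(0, 0), x = 0:1, y = 0)), "elapsed")
})

test_that("net displacement never exceeds path length", {
  set.seed(99)
  for (i in 1:100) {
    pts <- random_track_points(sample(2:30, 1), drift = runif(2, -1, 1),
                               sigma = runif(1, 0, 3))
    expect_lte(net_displacement(pts), path_length(pts) + 1e-12)
  }
  # equality iff collinear monotone motion
  col <- tibble::tibble(t = 0:3, x = c(0, 1, 2, 3), y = c(0, 2, 4, 6))
  expect_equal(net_displacement(col), path_length(col))
})

test_that("windowed metrics apply the minimum-point and first-window filters", {
  # track with 4 points in window 2 of a 2-window span: excluded from stats
  tr <- dplyr::bind_rows(
    tibble::tibble(track_id = "sparse", t = c(0, 20, 52, 54, 56, 58),
                   x = 1:6, y = 0),
    tibble::tibble(track_id = "dense", t = seq(0, 100, by = 10),
                   x = 0:10, y = 0)
  )
  ts <- align_at_onset(simple_ts(tr, onset = 0))
  m <- window_metrics(ts, n_windows = 2, min_points = 5)
  sparse2 <- m[m$track_id == "sparse" & m$window == 2, ]
  expect_equal(sparse2$n_points, 4)
  expect_false(sparse2$included) # below the 5-point threshold
  dense2 <- m[m$track_id == "dense" & m$window == 2, ]
  expect_true(dense2$included)
  # the entire first window is excluded by default, configurable
  expect_false(any(m$included[m$window == 1]))
  m_keep <- window_metrics(ts, n_windows = 2, min_points = 5,
                           exclude_first = FALSE)
  expect_true(m_keep$included[m_keep$track_id == "dense" &
                                m_keep$window == 1])
})

test_that("metrics and rose weights are invariant under rigid transforms", {
  set.seed(1234)
  geom <- upright_geom()
  pts <- random_track_points(40, drift = c(0.1, 0.3), sigma = 1.5)
  pts$track_id <- "1"
  base_rose <- rose_histogram(pts, geom, min_points = 5)
  for (i in 1:5) {
    theta <- runif(1, 0, 2 * pi)
    shift <- runif(2, -100, 100)
    xy <- rigid_xy(pts$x, pts$y, theta, shift)
    pts2 <- tibble::tibble(track_id = "1", t = pts$t,
                           x = xy[, 1], y = xy[, 2])
    g2 <- rigid_geom(geom, theta, shift)
    expect_equal(path_length(pts2), path_length(pts), tolerance = 1e-9)
    expect_equal(straightness(pts2), straightness(pts), tolerance = 1e-9)
    expect_equal(speed(pts2), speed(pts), tolerance = 1e-9)
    rose2 <- rose_histogram(pts2, g2, min_points = 5)
    expect_equal(rose2$proportion, base_rose$proportion, tolerance = 1e-9)
  }
})

test_that("rose histograms weight directions by displacement", {
  geom <- upright_geom()
  # all steps animal-ward: the animal bin holds everything
  up <- tibble::tibble(track_id = "1", t = 0:5, x = 0, y = seq(0, 50, by = 10))
  rose <- rose_histogram(up, geom)
  expect_equal(direction_proportion(rose, "animal"), 1)
  expect_equal(sum(rose$proportion), 1)
  # one 2-um animal step and one 2-um vegetal step in separate cells: 0.5/0.5
  two <- dplyr::bind_rows(
    tibble::tibble(track_id = "a", t = 0:4, x = 0,
                   y = c(0, 2, 2, 2, 2)),
    tibble::tibble(track_id = "b", t = 0:4, x = 10,
                   y = c(10, 8, 8, 8, 8))
  )
  rose2 <- rose_histogram(two, geom, min_points = 5)
  expect_equal(direction_proportion(rose2, "animal"), 0.5)
  expect_equal(direction_proportion(rose2, "vegetal"), 0.5)
  expect_equal(attr(rose2, "n_cells"), 2)
  # zero-magnitude steps are skipped, not errors
  expect_equal(sum(rose2$weight), 4)
  # an all-stationary segment has no direction information at all
  still <- tibble::tibble(track_id = "1", t = 0:5, x = 1, y = 1)
  expect_error(rose_histogram(still, geom), "no positive-magnitude")
})

test_that("rose weights are additive across arbitrary splits before normalization", {
  set.seed(555)
  geom <- upright_geom()
  pts <- purrr::map_dfr(1:6, function(i) {
    p <- random_track_points(12, drift = runif(2, -0.5, 0.5), sigma = 1)
    p$track_id <- as.character(i)
    p
  })
  whole <- rose_histogram(pts, geom, min_points = 5)
  part_a <- rose_histogram(pts[pts$track_id %in% c("1", "2", "3"), ], geom,
                           min_points = 5)
  part_b <- rose_histogram(pts[!pts$track_id %in% c("1", "2", "3"), ], geom,
                           min_points = 5)
  expect_equal(part_a$weight + part_b$weight, whole$weight, tolerance = 1e-9)
})

test_that("naive recomputation from raw rows matches the pipeline exactly", {
  set.seed(2024)
  geom <- upright_geom()
  for (i in 1:25) {
    pts <- random_track_points(sample(5:40, 1), drift = runif(2, -0.5, 0.5),
                               sigma = runif(1, 0.1, 2))
    pts$track_id <- "1"
    expect_equal(path_length(pts), naive_path_length(pts$x, pts$y),
                 tolerance = 1e-9)
    expect_equal(net_displacement(pts),
                 naive_net_displacement(pts$x, pts$y), tolerance = 1e-9)
    expect_equal(straightness(pts), naive_straightness(pts$x, pts$y),
                 tolerance = 1e-9)
    expect_equal(speed(pts), naive_speed(pts$t, pts$x, pts$y),
                 tolerance = 1e-9)
    rose <- rose_histogram(pts, geom, min_points = 5)
    expect_equal(rose$weight, naive_rose_weights(pts$x, pts$y, geom),
                 tolerance = 1e-9)
  }
})

test_that("group summaries report mean, SEM and cell counts", {
  base <- tibble::tibble(
    embryo_id = "e", genotype = "wildtype", track_id = "1", window = 2L,
    n_points = 10L, path_length = 1, net_displacement = 1,
    straightness = 0.8, speed = 1.5, included = TRUE
  )
  # a single cell: mean is that value, SEM flagged undefined and set to 0
  s1 <- summarize_by_genotype(base)
  expect_equal(s1$mean[s1$metric == "speed"], 1.5)
  expect_equal(s1$sem, c(0, 0))
  expect_false(any(s1$sem_defined))
  # duplicating the cohort under another label gives identical summaries
  dup <- dplyr::bind_rows(base, dplyr::mutate(base, genotype = "mutant"))
  s2 <- summarize_by_genotype(dup)
  expect_equal(s2$mean[s2$genotype == "mutant"],
               s2$mean[s2$genotype == "wildtype"])
  # simulated slow and fast cohorts are recovered within 3 SEM
  set.seed(31)
  cohorts <- purrr::map_dfr(c(slow = 1, fast = 2), function(mu) {
    tibble::tibble(
      embryo_id = "e", genotype = paste0("mu", mu),
      track_id = as.character(1:100), window = 2L, n_points = 10L,
      path_length = 1, net_displacement = 1, straightness = 0.5,
      speed = rnorm(100, mu, 0.3), included = TRUE
    )
  })
  s3 <- summarize_by_genotype(cohorts)
  sp <- s3[s3$metric == "speed", ]
  expect_lt(abs(sp$mean[sp$genotype == "mu1"] - 1),
            3 * sp$sem[sp$genotype == "mu1"])
  expect_lt(abs(sp$mean[sp$genotype == "mu2"] - 2),
            3 * sp$sem[sp$genotype == "mu2"])
  expect_warning(summarize_by_genotype(dplyr::mutate(base, included = FALSE)),
                 "no included")
})
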