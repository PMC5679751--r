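test_that("the TrackMate reader recovers tracks, points and times", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_trackmate_fixture(path, two_track_spots(), two_track_edges(),
                          timeinterval = 2)
  ts <- suppressMessages(read_trackmate_xml(path))
  expect_s3_class(ts, "track_set")
  expect_equal(dplyr::n_distinct(ts$tracks$track_id), 2)
  expect_equal(as.integer(table(ts$tracks$track_id)), c(3L, 3L))
  expect_equal(ts$frame_interval, 2)
  # frame indices converted to minutes with the declared interval
  t0 <- sort(ts$tracks$t[ts$tracks$track_id == "0"])
  expect_equal(t0, c(0, 2, 4))
  # an explicit frame interval overrides the declared one
  ts3 <- suppressMessages(read_trackmate_xml(path, frame_interval = 3))
  expect_equal(sort(unique(ts3$tracks$t)), c(0, 3, 6))
})

test_that("a lone spot with no edges is a legal one-point track", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_trackmate_fixture(
    path, data.frame(id = "s1", frame = 0, x = 1, y = 2),
    data.frame(track = character(), source = character(),
               target = character())
  )
  ts <- suppressMessages(read_trackmate_xml(path))
  expect_equal(dplyr::n_distinct(ts$tracks$track_id), 1)
  expect_equal(nrow(ts$tracks), 1)
  expect_equal(ts$tracks$x, 1)
})

test_that("malformed TrackMate files fail with named elements", {
  spots <- two_track_spots()
  edges <- two_track_edges()
  # non-monotone times within one track (two linked spots in the same frame)
  p1 <- withr::local_tempfile(fileext = ".xml")
  bad <- spots
  bad$frame[2] <- 0
  write_trackmate_fixture(p1, bad, edges)
  expect_error(suppressMessages(read_trackmate_xml(p1)), "non-monotone")
  # duplicate spot ids
  p2 <- withr::local_tempfile(fileext = ".xml")
  dup <- spots
  dup$id[2] <- "a1"
  write_trackmate_fixture(p2, dup, edges[-c(1, 2), ])
  expect_error(suppressMessages(read_trackmate_xml(p2)), "duplicate spot")
  # merges are rejected
  p3 <- withr::local_tempfile(fileext = ".xml")
  merge_edges <- data.frame(
    track = "0", source = c("a1", "b1", "a2"), target = c("a2", "a2", "a3")
  )
  write_trackmate_fixture(p3, spots, merge_edges)
  expect_error(suppressMessages(read_trackmate_xml(p3)), "merge")
  # missing sections are named
  p4 <- withr::local_tempfile(fileext = ".xml")
  writeLines('<TrackMate version="7"><Model></Model></TrackMate>', p4)
  expect_error(suppressMessages(read_trackmate_xml(p4)), "AllSpots")
})

test_that("divisions split into child tracks carrying parent ids", {
  path <- withr::local_tempfile(fileext = ".xml")
  spots <- data.frame(
    id = c("r1", "r2", "d1", "d2", "e1", "e2"),
    frame = c(0, 1, 2, 3, 2, 3),
    x = c(0, 1, 2, 3, 2.5, 3.5),
    y = 0
  )
  edges <- data.frame(
    track = "0",
    source = c("r1", "r2", "r2", "d1", "e1"),
    target = c("r2", "d1", "e1", "d2", "e2")
  )
  write_trackmate_fixture(path, spots, edges)
  ts <- suppressMessages(read_trackmate_xml(path))
  per <- dplyr::distinct(ts$tracks, .data$track_id, .data$parent_id,
                         .data$fate)
  expect_equal(nrow(per), 3)
  expect_equal(sum(per$fate == "divided"), 1)
  children <- per[!is.na(per$parent_id), ]
  expect_equal(nrow(children), 2)
  expect_equal(unique(children$parent_id), "0")
})

test_that("z coordinates are read and dropped with a warning", {
  path <- withr::local_tempfile(fileext = ".xml")
  spots <- two_track_spots()
  spots$z <- 7
  write_trackmate_fixture(path, spots, two_track_edges())
  expect_warning(ts <- suppressMessages(read_trackmate_xml(path)), "Z")
  expect_false("z" %in% names(ts$tracks))
})

test_that("CSV write-then-read is the identity on track sets", {
  p <- sim_params(n_cells = 12, duration = 40, seed = 5,
                  division_prob_per_window = 0.2)
  ts <- simulate_tracks(p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(ts, path)
  ts2 <- read_tracks_csv(path, frame_interval = ts$frame_interval,
                         internalization_onset = 0)
  a <- dplyr::arrange(ts$tracks, .data$track_id, .data$t)
  b <- dplyr::arrange(ts2$tracks, .data$track_id, .data$t)
  expect_equal(b$t, a$t, tolerance = 1e-6)
  expect_equal(b$x, a$x, tolerance = 1e-6)
  expect_equal(b$y, a$y, tolerance = 1e-6)
  expect_equal(b$fate, a$fate)
  expect_equal(b$parent_id, a$parent_id)
})

test_that("CSV schema errors and orderings behave as declared", {
  # missing columns are listed by name
  p1 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(track_id = "1", t_min = 0), p1)
  expect_error(read_tracks_csv(p1), "x, y")
  # empty file with header: zero tracks
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("track_id,t_min,x,y", p2)
  ts <- read_tracks_csv(p2)
  expect_equal(nrow(ts$tracks), 0)
  # rows out of time order: reordered with a warning
  p3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    track_id = "1", t_min = c(4, 0, 2), x = c(3, 1, 2), y = 0
  ), p3)
  expect_warning(ts3 <- read_tracks_csv(p3), "reordered")
  expect_equal(ts3$tracks$t, c(0, 2, 4))
  expect_equal(ts3$tracks$x, c(1, 2, 3))
})

test_that("XML and CSV readers agree on equivalent fixtures", {
  xml_path <- withr::local_tempfile(fileext = ".xml")
  write_trackmate_fixture(xml_path, two_track_spots(), two_track_edges(),
                          timeinterval = 2)
  from_xml <- suppressMessages(read_trackmate_xml(xml_path))

  csv_path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    track_id = rep(c("0", "1"), each = 3),
    t_min = rep(c(0, 2, 4), 2),
    x = c(0, 1, 2, 10, 11, 12),
    y = rep(c(0, 5), each = 3)
  ), csv_path)
  from_csv <- read_tracks_csv(csv_path, frame_interval = 2)

  a <- dplyr::arrange(from_xml$tracks, .data$track_id, .data$t)
  b <- dplyr::arrange(from_csv$tracks, .data$track_id, .data$t)
  expect_equal(a$t, b$t)
  expect_equal(a$x, b$x)
  expect_equal(a$y, b$y)
  expect_equal(a$track_id, b$track_id)
})

test_that("track sets validate their invariants", {
  expect_error(
    track_set(tibble::tibble(track_id = "1", t = c(0, 0), x = 1:2, y = 0)),
    "strictly increasing"
  )
  expect_error(
    track_set(tibble::tibble(track_id = "1", t = 0, x = 1, y = 1),
              frame_interval = 0),
    "frame_interval"
  )
})
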