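#' Read a TrackMate-style XML track file
#'
#' Parses the stable spot/edge core of the TrackMate export schema: spots
#' with `POSITION_X`/`POSITION_Y` (and `FRAME` or `POSITION_T` as frame
#' index) under `Model/AllSpots`, and per-track edge lists under
#' `Model/AllTracks`. Features, filters and view settings are ignored --
#' the downstream migration analysis consumes none of them.
#'
#' Divisions appear in TrackMate as a spot with two outgoing edges; the
#' parent track is ended there (fate `"divided"`) and each branch becomes a
#' child track carrying `parent_id`. Merges (a spot with two incoming edges)
#' do not occur in this biology and are rejected. Spots referenced by no
#' edge become single-point tracks. `POSITION_Z`, if present and non-zero,
#' is dropped with a warning: the analysis runs on lateral-view 2D
#' projections.
#'
#' @param path Path to the XML file.
#' @param frame_interval Minutes between frames; if `NULL`, taken from the
#'   `Settings/ImageData` `timeinterval` attribute, defaulting to 1.
#' @inheritParams track_set
#' @return A [track_set()].
#' @export
read_trackmate_xml <- function(path, frame_interval = NULL, geometry = NULL,
                               embryo_id = "embryo", genotype = "wildtype",
                               internalization_onset = NA_real_) {
  doc <- xml2::read_xml(path)
  version <- xml2::xml_attr(doc, "version")
  if (!is.na(version)) message("TrackMate file declares version ", version)

  model <- xml2::xml_find_first(doc, ".//Model")
  if (inherits(model, "xml_missing")) {
    stop("parse error: missing <Model> element", call. = FALSE)
  }
  all_spots <- xml2::xml_find_first(model, "./AllSpots")
  if (inherits(all_spots, "xml_missing")) {
    stop("parse error: missing <AllSpots> element", call. = FALSE)
  }
  all_tracks <- xml2::xml_find_first(model, "./AllTracks")
  if (inherits(all_tracks, "xml_missing")) {
    stop("parse error: missing <AllTracks> element", call. = FALSE)
  }
  if (is.null(frame_interval)) {
    ti <- xml2::xml_attr(
      xml2::xml_find_first(doc, ".//Settings/ImageData"), "timeinterval"
    )
    frame_interval <- if (length(ti) && !is.na(ti)) as.numeric(ti) else 1
  }

  spots <- xml2::xml_find_all(all_spots, ".//Spot")
  if (!length(spots)) {
    return(track_set(
      tibble::tibble(track_id = character(), t = numeric(),
                     x = numeric(), y = numeric()),
      geometry = geometry, embryo_id = embryo_id, genotype = genotype,
      internalization_onset = internalization_onset,
      frame_interval = frame_interval
    ))
  }
  spot_id <- xml2::xml_attr(spots, "ID")
  if (anyDuplicated(spot_id)) {
    stop("parse error: duplicate spot ID(s): ",
         paste(unique(spot_id[duplicated(spot_id)]), collapse = ", "),
         call. = FALSE)
  }
  frame <- suppressWarnings(as.numeric(xml2::xml_attr(spots, "FRAME")))
  if (all(is.na(frame))) {
    frame <- suppressWarnings(as.numeric(xml2::xml_attr(spots, "POSITION_T")))
  }
  spot_tab <- tibble::tibble(
    id = spot_id,
    x = as.numeric(xml2::xml_attr(spots, "POSITION_X")),
    y = as.numeric(xml2::xml_attr(spots, "POSITION_Y")),
    z = suppressWarnings(as.numeric(xml2::xml_attr(spots, "POSITION_Z"))),
    t = frame * frame_interval
  )
  if (any(!is.na(spot_tab$z) & spot_tab$z != 0)) {
    warning("POSITION_Z present; z coordinates dropped ",
            "(analysis is on 2D lateral-view projections)", call. = FALSE)
  }

  track_nodes <- xml2::xml_find_all(all_tracks, "./Track")
  rows <- list()
  used_spots <- character()
  for (tn in track_nodes) {
    tid <- xml2::xml_attr(tn, "TRACK_ID")
    if (is.na(tid)) tid <- xml2::xml_attr(tn, "name")
    edges <- xml2::xml_find_all(tn, "./Edge")
    src <- xml2::xml_attr(edges, "SPOT_SOURCE_ID")
    dst <- xml2::xml_attr(edges, "SPOT_TARGET_ID")
    unknown <- setdiff(c(src, dst), spot_tab$id)
    if (length(unknown)) {
      stop("parse error: edge references unknown spot ID(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(dst)) {
      stop("track ", tid, " contains a merge (spot with two incoming edges); ",
           "merges are not supported", call. = FALSE)
    }
    used_spots <- c(used_spots, src, dst)
    rows <- c(rows, linearize_track(tid, src, dst, spot_tab))
  }
  # unlinked spots become single-point tracks
  lone <- setdiff(spot_tab$id, used_spots)
  for (id in lone) {
    s <- spot_tab[spot_tab$id == id, ]
    rows <- c(rows, list(tibble::tibble(
      track_id = paste0("spot_", id), t = s$t, x = s$x, y = s$y,
      parent_id = NA_character_, fate = "alive"
    )))
  }
  tracks <- dplyr::bind_rows(rows)
  track_set(tracks, geometry = geometry, embryo_id = embryo_id,
            genotype = genotype,
            internalization_onset = internalization_onset,
            frame_interval = frame_interval)
}

# walk one TrackMate track's edge list, splitting at divisions
linearize_track <- function(tid, src, dst, spot_tab) {
  succ <- split(dst, src)
  roots <- setdiff(src, dst)
  if (!length(roots)) {
    stop("track ", tid, " has no root spot (cyclic edges?)", call. = FALSE)
  }
  out <- list()
  walk <- function(start_id, track_id, parent_id) {
    chain <- start_id
    cur <- start_id
    fate <- "alive"
    repeat {
      nxt <- succ[[cur]]
      if (is.null(nxt)) break
      if (length(nxt) == 1) {
        chain <- c(chain, nxt)
        cur <- nxt
      } else {
        fate <- "divided"
        for (k in seq_along(nxt)) {
          walk(nxt[k], paste0(track_id, ".", k), track_id)
        }
        break
      }
    }
    idx <- match(chain, spot_tab$id)
    tt <- spot_tab$t[idx]
    ord <- order(tt)
    if (any(diff(tt) <= 0)) {
      # edge order may be arbitrary in the file; only truly non-monotone
      # times (ties or reversals after sorting) are an error
      if (any(diff(tt[ord]) <= 0)) {
        stop("track ", track_id, " has non-monotone spot times", call. = FALSE)
      }
      chain <- chain[ord]
      idx <- idx[ord]
      tt <- tt[ord]
    }
    out[[length(out) + 1]] <<- tibble::tibble(
      track_id = track_id, t = tt,
      x = spot_tab$x[idx], y = spot_tab$y[idx],
      parent_id = parent_id, fate = fate
    )
  }
  if (length(roots) == 1) {
    walk(roots, tid, NA_character_)
  } else {
    for (k in seq_along(roots)) walk(roots[k], paste0(tid, ".", k), NA_character_)
  }
  out
}

#' Read and write cell tracks as CSV
#'
#' The plain-text track dialect: comma-separated, header row, UTF-8, `.`
#' decimal, one row per spot with columns `track_id`, `t_min`, `x`, `y` and
#' optionally `parent_id` and `fate`. `write_tracks_csv()` followed by
#' `read_tracks_csv()` reproduces the track set point-by-point.
#'
#' @param path File path.
#' @param frame_interval Minutes between frames (metadata; default 2).
#' @inheritParams track_set
#' @return `read_tracks_csv()` returns a [track_set()];
#'   `write_tracks_csv()` invisibly returns `path`.
#' @export
read_tracks_csv <- function(path, geometry = NULL, embryo_id = "embryo",
                            genotype = "wildtype",
                            internalization_onset = NA_real_,
                            frame_interval = 2) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("track_id", "t_min", "x", "y"), "track CSV")
  if ("z" %in% names(df)) {
    if (any(!is.na(df$z) & df$z != 0)) {
      warning("z column present; dropped (2D lateral-view analysis)",
              call. = FALSE)
    }
    df$z <- NULL
  }
  df <- dplyr::rename(df, t = "t_min")
  df$track_id <- as.character(df$track_id)
  if ("parent_id" %in% names(df)) df$parent_id <- as.character(df$parent_id)
  if ("fate" %in% names(df)) df$fate <- as.character(df$fate)
  if (nrow(df)) {
    disordered <- df |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(bad = is.unsorted(.data$t, strictly = FALSE)) |>
      dplyr::filter(.data$bad)
    if (nrow(disordered)) {
      warning("rows out of time order in track(s) ",
              paste(disordered$track_id, collapse = ", "),
              "; reordered by time", call. = FALSE)
      df <- dplyr::arrange(df, .data$track_id, .data$t)
    }
  }
  track_set(df, geometry = geometry, embryo_id = embryo_id,
            genotype = genotype,
            internalization_onset = internalization_onset,
            frame_interval = frame_interval)
}

#' @param ts A [track_set()].
#' @rdname read_tracks_csv
#' @export
write_tracks_csv <- function(ts, path) {
  stopifnot(is_track_set(ts))
  out <- ts$tracks |>
    dplyr::select("track_id", t_min = "t", "x", "y", "parent_id", "fate")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
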