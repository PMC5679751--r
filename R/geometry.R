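#' Embryo coordinate frame from landmark annotations
#'
#' Defines the lateral-view coordinate frame of a gastrula-stage embryo from
#' the annotated animal pole, vegetal pole and a dorsal reference point, plus
#' the measured embryo height and width. All downstream position metrics
#' (percent embryo height, lateral offset, anatomical movement angles) are
#' expressed in this frame. The lateral view is treated as a flat 2D plane,
#' matching what measurements on maximum-intensity projections deliver; no
#' spherical correction is applied.
#'
#' @param animal,vegetal Numeric length-2 vectors, image coordinates (µm) of
#'   the animal and vegetal poles.
#' @param dorsal Numeric length-2 vector, any point on the dorsal side of the
#'   animal-vegetal axis; only the side it falls on is used to orient the
#'   dorsal direction.
#' @param width Lateral extent of the embryo perpendicular to the
#'   animal-vegetal axis, in µm. Must be positive.
#' @param height Embryo height (animal-to-vegetal extent), in µm. Defaults to
#'   the distance between the two pole landmarks.
#' @param lateral_center Numeric length-2 vector, center of the lateral side
#'   (the point 90 degrees around the embryo from dorsal). In the lateral
#'   view this projects onto the animal-vegetal axis, so it defaults to the
#'   midpoint of the pole-to-pole segment.
#' @param unit Unit of the coordinates; everything internal is µm.
#'
#' @return An object of class `embryo_geometry`: a list holding the
#'   landmarks, dimensions, and the derived unit vectors of the animal and
#'   dorsal directions.
#'
#' @examples
#' geom <- embryo_geometry(
#'   animal = c(0, 700), vegetal = c(0, 0), dorsal = c(350, 350), width = 700
#' )
#' relative_height(0, 700, geom) # 100: the animal pole
#' @export
embryo_geometry <- function(animal, vegetal, dorsal, width,
                            height = NULL, lateral_center = NULL,
                            unit = "um") {
  animal <- as.numeric(animal)
  vegetal <- as.numeric(vegetal)
  dorsal <- as.numeric(dorsal)
  stopifnot(length(animal) == 2, length(vegetal) == 2, length(dorsal) == 2)
  axis <- animal - vegetal
  axis_len <- sqrt(sum(axis^2))
  if (axis_len <= 0) {
    stop("animal and vegetal poles coincide; no animal-vegetal axis", call. = FALSE)
  }
  if (is.null(height)) height <- axis_len
  if (!is.numeric(height) || height <= 0) stop("height must be > 0", call. = FALSE)
  if (!is.numeric(width) || width <= 0) stop("width must be > 0", call. = FALSE)

  axis_animal <- axis / axis_len
  # perpendicular of the AV axis, signed toward the dorsal reference
  perp <- c(-axis_animal[2], axis_animal[1])
  side <- sum(perp * (dorsal - vegetal))
  if (abs(side) < 1e-9 * axis_len) {
    stop("dorsal reference lies on the animal-vegetal axis; ",
         "dorsal direction is not resolvable", call. = FALSE)
  }
  axis_dorsal <- perp * sign(side)
  if (is.null(lateral_center)) lateral_center <- (animal + vegetal) / 2
  lateral_center <- as.numeric(lateral_center)
  stopifnot(length(lateral_center) == 2)

  structure(
    list(
      animal = animal, vegetal = vegetal, dorsal = dorsal,
      height = height, width = width,
      lateral_center = lateral_center,
      axis_animal = axis_animal, axis_dorsal = axis_dorsal,
      axis_length = axis_len, unit = unit
    ),
    class = "embryo_geometry"
  )
}

#' @export
print.embryo_geometry <- function(x, ...) {
  cat("<embryo_geometry>\n")
  cat(sprintf("  animal pole  : (%.1f, %.1f)\n", x$animal[1], x$animal[2]))
  cat(sprintf("  vegetal pole : (%.1f, %.1f)\n", x$vegetal[1], x$vegetal[2]))
  cat(sprintf("  height x width: %.1f x %.1f %s\n", x$height, x$width, x$unit))
  invisible(x)
}

is_embryo_geometry <- function(x) inherits(x, "embryo_geometry")

#' Position along the animal-vegetal axis as percent embryo height
#'
#' Projects positions onto the animal-vegetal axis and scales them so the
#' vegetal pole maps to 0 and the animal pole to 100. Positions projecting
#' slightly outside the axis (within `tol` percent) are clamped; anything
#' further out is an error, since it cannot lie on the embryo.
#'
#' @param x,y Numeric vectors of image coordinates (µm).
#' @param geom An [embryo_geometry()].
#' @param tol Out-of-embryo tolerance as percent of embryo height (default 1).
#' @return Numeric vector of percent embryo height in \[0, 100\].
#' @export
relative_height <- function(x, y, geom, tol = 1) {
  stopifnot(is_embryo_geometry(geom))
  pct <- relative_height_unchecked(x, y, geom)
  bad <- pct < -tol | pct > 100 + tol
  if (any(bad, na.rm = TRUE)) {
    stop(sprintf(
      "%d position(s) project outside the embryo (beyond [%g, %g]%% height)",
      sum(bad, na.rm = TRUE), -tol, 100 + tol
    ), call. = FALSE)
  }
  pmin(pmax(pct, 0), 100)
}

#' Signed lateral offset as a fraction of embryo width
#'
#' Perpendicular distance from the animal-vegetal axis through the lateral
#' center, divided by the embryo width. The sign is positive toward dorsal.
#' A cell "on or within 10% of the embryo width from the center of the
#' lateral side" has `abs(lateral_offset) <= 0.10`.
#'
#' @inheritParams relative_height
#' @return Numeric vector of signed width fractions.
#' @export
lateral_offset <- function(x, y, geom) {
  stopifnot(is_embryo_geometry(geom))
  ((x - geom$lateral_center[1]) * geom$axis_dorsal[1] +
     (y - geom$lateral_center[2]) * geom$axis_dorsal[2]) / geom$width
}

#' Anatomical direction convention for movement angles
#'
#' Maps the four cardinal anatomical directions (animal, dorsal, vegetal,
#' ventral) to angles at 90-degree spacing. The default places dorsal at 0
#' and animal at 90 degrees, increasing counter-clockwise, matching
#' compass-style rose plots labelled A/D/Vg/V.
#'
#' @param zero_axis Which anatomical direction maps to angle 0; one of
#'   `"dorsal"`, `"animal"`, `"vegetal"`, `"ventral"`.
#' @param orientation `"ccw"` (counter-clockwise, default) or `"cw"`.
#' @return An object of class `direction_convention`.
#' @export
direction_convention <- function(zero_axis = "dorsal", orientation = "ccw") {
  zero_axis <- match.arg(zero_axis, c("dorsal", "animal", "vegetal", "ventral"))
  orientation <- match.arg(orientation, c("ccw", "cw"))
  base <- c(dorsal = 0, animal = 90, ventral = 180, vegetal = 270)
  sgn <- if (orientation == "ccw") 1 else -1
  angles <- (sgn * (base - base[[zero_axis]])) %% 360
  structure(
    list(zero_axis = zero_axis, orientation = orientation, labels = angles),
    class = "direction_convention"
  )
}

#' @export
print.direction_convention <- function(x, ...) {
  cat("<direction_convention>", x$orientation, "\n")
  print(x$labels)
  invisible(x)
}

#' Movement angle of displacement steps in the anatomical frame
#'
#' Expresses displacement vectors as angles in the embryo's anatomical frame
#' defined by `geom` (animal and dorsal unit axes) under a
#' [direction_convention()]. Scaling a step by any positive factor leaves its
#' angle unchanged. Zero-length steps have no direction and raise an error;
#' callers accumulating directional statistics skip them (their weight is
#' zero anyway).
#'
#' @param dx,dy Numeric vectors, displacement components in image coordinates.
#' @param geom An [embryo_geometry()].
#' @param conv A [direction_convention()].
#' @return Numeric vector of angles in degrees in \[0, 360).
#' @export
movement_angle <- function(dx, dy, geom, conv = direction_convention()) {
  stopifnot(is_embryo_geometry(geom), inherits(conv, "direction_convention"))
  if (any(dx == 0 & dy == 0)) {
    stop("zero-length step has no direction; skip zero steps before calling",
         call. = FALSE)
  }
  a <- dx * geom$axis_animal[1] + dy * geom$axis_animal[2]
  d <- dx * geom$axis_dorsal[1] + dy * geom$axis_dorsal[2]
  # angle in the default frame: dorsal = 0, animal = 90, ccw
  phi <- (atan2(a, d) * 180 / pi) %% 360
  sgn <- if (conv$orientation == "ccw") 1 else -1
  base <- c(dorsal = 0, animal = 90, ventral = 180, vegetal = 270)
  (sgn * (phi - base[[conv$zero_axis]])) %% 360
}

#' Annotate cell positions with embryo-normalized coordinates
#'
#' Adds `relative_height` (percent embryo height) and `lateral_offset`
#' (signed fraction of embryo width) columns to a table of cell coordinates.
#'
#' @param cells A data frame with numeric `x` and `y` columns (µm).
#' @param geom An [embryo_geometry()], or a landmark table as returned by
#'   [read_landmarks()] when `cells` has an `embryo_id` column.
#' @param tol Out-of-embryo tolerance in percent height, see
#'   [relative_height()].
#' @param clip If `TRUE`, silently drop cells projecting outside the embryo
#'   (beyond `tol`) instead of erroring; a warning reports how many.
#' @return A tibble: `cells` plus `relative_height` and `lateral_offset`.
#' @export
annotate_positions <- function(cells, geom, tol = 1, clip = FALSE) {
  cells <- tibble::as_tibble(cells)
  require_columns(cells, c("x", "y"), "cell table")
  if (is.data.frame(geom)) {
    require_columns(cells, "embryo_id", "cell table (landmark-table geometry)")
    parts <- dplyr::group_split(dplyr::group_by(cells, .data$embryo_id))
    out <- purrr::map(parts, function(part) {
      id <- part$embryo_id[1]
      g <- geometry_for_embryo(geom, id)
      if (is.null(g)) {
        warning("no landmarks for embryo '", id, "'; skipped", call. = FALSE)
        return(NULL)
      }
      annotate_positions(part, g, tol = tol, clip = clip)
    })
    return(dplyr::bind_rows(out))
  }
  stopifnot(is_embryo_geometry(geom))
  if (clip) {
    proj <- relative_height_unchecked(cells$x, cells$y, geom)
    bad <- proj < -tol | proj > 100 + tol
    if (any(bad)) {
      warning(sum(bad), " cell(s) project outside the embryo; dropped",
              call. = FALSE)
      cells <- cells[!bad, , drop = FALSE]
    }
  }
  dplyr::mutate(
    cells,
    relative_height = relative_height(.data$x, .data$y, geom, tol = tol),
    lateral_offset = lateral_offset(.data$x, .data$y, geom)
  )
}

relative_height_unchecked <- function(x, y, geom) {
  # projection via the squared axis norm: numerator and denominator are the
  # same expression at the poles, so relative_height(animal) is exactly 100
  # and relative_height(vegetal) exactly 0 in floating point
  ax <- geom$animal[1] - geom$vegetal[1]
  ay <- geom$animal[2] - geom$vegetal[2]
  100 * (((x - geom$vegetal[1]) * ax + (y - geom$vegetal[2]) * ay) /
           (ax * ax + ay * ay))
}

#' Read embryo landmark annotations
#'
#' Reads the landmark sidecar table shared by the position and tracking
#' analyses: one row per embryo with pole and dorsal-reference coordinates
#' and the measured embryo height and width.
#'
#' @param path Path to a CSV or JSON file with columns/fields `embryo_id`,
#'   `genotype`, `animal_x`, `animal_y`, `vegetal_x`, `vegetal_y`,
#'   `dorsal_x`, `dorsal_y`, `height`, `width` and optionally `unit`.
#' @return A tibble with one row per embryo and a `geometry` list-column of
#'   [embryo_geometry()] objects.
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
  }
  require_columns(df, c(
    "embryo_id", "animal_x", "animal_y", "vegetal_x", "vegetal_y",
    "dorsal_x", "dorsal_y", "height", "width"
  ), "landmark table")
  df$geometry <- purrr::pmap(
    list(df$animal_x, df$animal_y, df$vegetal_x, df$vegetal_y,
         df$dorsal_x, df$dorsal_y, df$height, df$width),
    function(ax, ay, vx, vy, dx, dy, h, w) {
      embryo_geometry(c(ax, ay), c(vx, vy), c(dx, dy),
                      width = w, height = h,
                      unit = if ("unit" %in% names(df)) df$unit[1] else "um")
    }
  )
  df
}

geometry_for_embryo <- function(landmarks, embryo_id) {
  i <- match(embryo_id, landmarks$embryo_id)
  if (is.na(i)) return(NULL)
  landmarks$geometry[[i]]
}
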