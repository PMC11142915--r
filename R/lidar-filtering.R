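#' Quality-filter thresholds for lidar canopy-height observations
#'
#' Thresholds of the seven retention predicates applied to ATL08-style
#' segment observations, plus the height cap. Boundary semantics follow the
#' stated inequality directions literally: strict `<` for solar elevation,
#' height difference from reference elevation and vertical geolocation
#' error; `<=` for the 30 m height-validity bound.
#'
#' @param solar_elev_max Solar elevation must be below this (degrees).
#' @param rh98_max_valid Upper bound of a valid RH98 (m, inclusive).
#' @param landcover_height_max Named numeric map from landcover class to its
#'   class-specific maximum valid height (m). Classes absent from the map
#'   fall back to `rh98_max_valid` (or are rejected, see
#'   `unknown_landcover`).
#' @param height_diff_max Height difference from reference elevation must be
#'   below this (m).
#' @param geoloc_error_max Total vertical geolocation error must be below
#'   this (m).
#' @param cap Height cap applied after filtering (m).
#' @param unknown_landcover What to do with a class absent from
#'   `landcover_height_max`: `"fallback"` uses `rh98_max_valid`,
#'   `"reject"` fails the predicate.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(solar_elev_max = 5, rh98_max_valid = 30,
                              landcover_height_max = numeric(0),
                              height_diff_max = 25, geoloc_error_max = 2.5,
                              cap = 30,
                              unknown_landcover = c("fallback", "reject")) {
  unknown_landcover <- match.arg(unknown_landcover)
  vals <- c(solar_elev_max, rh98_max_valid, height_diff_max,
            geoloc_error_max, cap)
  if (any(vals <= 0)) stop("all thresholds must be positive")
  if (length(landcover_height_max) &&
      any(landcover_height_max > rh98_max_valid))
    stop("landcover height thresholds must not exceed rh98_max_valid")
  structure(list(solar_elev_max = solar_elev_max,
                 rh98_max_valid = rh98_max_valid,
                 landcover_height_max = landcover_height_max,
                 height_diff_max = height_diff_max,
                 geoloc_error_max = geoloc_error_max,
                 cap = cap, unknown_landcover = unknown_landcover),
            class = "filter_thresholds")
}

point_fields <- function() {
  c("rh98", "beam", "snow_flag", "cloud_flag", "solar_elevation",
    "landcover_class", "height_diff_ref", "geoloc_error")
}

check_point_fields <- function(points, fields) {
  missing <- setdiff(fields, names(points))
  if (length(missing))
    stop("point table is missing required field(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Names of the seven quality predicates
#' @return Character vector of length 7, in application order.
#' @export
filter_predicates <- function() {
  c("strong_beam", "snow_free", "cloud_free", "solar", "rh98_valid",
    "height_diff", "geoloc")
}

# logical pass matrix, one column per predicate
predicate_matrix <- function(points, t) {
  n <- nrow(points)
  lc_max <- rep(t$rh98_max_valid, n)
  if (length(t$landcover_height_max)) {
    known <- points$landcover_class %in% names(t$landcover_height_max)
    lc_max[known] <- t$landcover_height_max[points$landcover_class[known]]
    if (t$unknown_landcover == "reject") lc_max[!known] <- -Inf
  } else if (t$unknown_landcover == "reject") {
    lc_max[] <- -Inf
  }
  cbind(strong_beam = points$beam == "strong",
        snow_free = !points$snow_flag,
        cloud_free = !points$cloud_flag,
        solar = points$solar_elevation < t$solar_elev_max,
        rh98_valid = points$rh98 <= t$rh98_max_valid & points$rh98 <= lc_max,
        height_diff = points$height_diff_ref < t$height_diff_max,
        geoloc = points$geoloc_error < t$geoloc_error_max)
}

#' Apply the seven quality predicates to a point table
#'
#' A point is retained iff it passes all seven predicates: strong beam,
#' snow-free surface, cloud-free conditions, night/low-light acquisition
#' (solar elevation below 5 degrees), a valid RH98 (at most 30 m and at
#' most the landcover-specific maximum), height difference from reference
#' elevation below 25 m, and total vertical geolocation error below 2.5 m.
#' Removal counts attribute every rejected point to each predicate it
#' fails, so counts can exceed the number of removed points.
#'
#' @param points Data frame of canopy points (see [gen_canopy_points()] for
#'   the schema). Missing fields are a hard error naming the field.
#' @param thresholds A [filter_thresholds()].
#' @return List with `points` (retained rows), `removal_counts` (named
#'   integer vector per predicate), `n_input`, `n_retained`, `n_removed`.
#' @export
filter_points <- function(points, thresholds = filter_thresholds()) {
  check_point_fields(points, point_fields())
  pm <- predicate_matrix(points, thresholds)
  keep <- rowSums(pm) == ncol(pm)
  list(points = points[keep, , drop = FALSE],
       removal_counts = colSums(!pm),
       n_input = nrow(points),
       n_retained = sum(keep),
       n_removed = sum(!keep))
}

#' Zero out flagged canopy heights
#'
#' Sets RH98 to 0 m for points carrying the canopy-height flag marking
#' assumed-erroneous heights (typically over barren ground and tundra at
#' the cold edge of the domain, where spuriously tall returns would bias
#' the training data). No points are dropped; the operation is idempotent.
#'
#' @param points Data frame with `rh98` and `height_flagged`.
#' @return The point table with flagged heights zeroed.
#' @export
apply_height_flag <- function(points) {
  check_point_fields(points, c("rh98", "height_flagged"))
  points$rh98[points$height_flagged] <- 0
  points
}

#' Cap canopy heights
#'
#' Assigns `cap` (default 30 m) to observations above it, mitigating
#' spurious tall outliers. Idempotent.
#'
#' @param points Data frame with `rh98`.
#' @param cap Height cap (m, > 0).
#' @return The point table with `rh98 = min(rh98, cap)`.
#' @export
cap_heights <- function(points, cap = 30) {
  if (cap <= 0) stop("cap must be positive")
  check_point_fields(points, "rh98")
  points$rh98 <- pmin(points$rh98, cap)
  points
}

#' Grid point heights with the maximum-aggregation rule
#'
#' Each grid cell takes the maximum RH98 over all points whose coordinates
#' fall inside it (half-open cells, see [cell_index()]), so the cell
#' estimates the tallest canopy observed there. Cells containing no points
#' are nodata. Points outside the grid extent are counted and skipped.
#'
#' @param points Data frame with `lon`, `lat`, `rh98`.
#' @param spec A [grid_spec()] defining the target grid.
#' @return List with `grid` (a [raster_grid()]), `n_occupied`,
#'   `n_points_used`, `n_points_outside`.
#' @export
grid_max <- function(points, spec) {
  if (spec$nrow < 1 || spec$ncol < 1) stop("degenerate grid")
  check_point_fields(points, c("lon", "lat", "rh98"))
  idx <- cell_index(spec, points$lon, points$lat)
  inside <- !is.na(idx$row)
  vals <- matrix(NA_real_, spec$nrow, spec$ncol)
  if (any(inside)) {
    flat <- (idx$col[inside] - 1L) * spec$nrow + idx$row[inside]
    mx <- tapply(points$rh98[inside], flat, max)
    vals[as.integer(names(mx))] <- mx
  }
  list(grid = raster_grid(vals, spec, name = "max_rh98"),
       n_occupied = sum(!is.na(vals)),
       n_points_used = sum(inside),
       n_points_outside = sum(!inside))
}

#' Filter, flag, cap and grid in the standard order
#'
#' Convenience composition: [filter_points()], then [apply_height_flag()],
#' then [cap_heights()], then [grid_max()].
#'
#' @param points Canopy point table.
#' @param spec Target [grid_spec()].
#' @param thresholds A [filter_thresholds()].
#' @return List with `gridded` (the [grid_max()] result), `filtered` (the
#'   [filter_points()] result) and `points` (the retained, flagged, capped
#'   table).
#' @export
prepare_height_grid <- function(points, spec,
                                thresholds = filter_thresholds()) {
  fl <- filter_points(points, thresholds)
  pts <- cap_heights(apply_height_flag(fl$points), thresholds$cap)
  list(gridded = grid_max(pts, spec), filtered = fl, points = pts)
}
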