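#' Read and write canopy point tables as CSV
#'
#' Plain-text interchange for ATL08-style point tables; all predicate
#' fields (see [filter_points()]) round-trip unchanged.
#'
#' @param points Point data frame.
#' @param path File path.
#' @return `read_points_csv()` returns the point data frame.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (f in intersect(c("snow_flag", "cloud_flag", "height_flagged"), names(pts)))
    pts[[f]] <- as.logical(pts[[f]])
  pts
}

#' Write a raster layer to TIFF with a JSON georeferencing sidecar
#'
#' Writes the layer as a two-channel 32-bit TIFF (requires the `tiff`
#' package): channel 1 holds the values min-max normalised to \[0, 1\] (the
#' format's sample range), channel 2 a validity mask for nodata. The
#' `<path>.json` sidecar records the grid geometry and the value range,
#' since plain TIFF carries neither.
#'
#' @param raster A [raster_grid()].
#' @param path Output path (`.tif`).
#' @return `read_raster_tif()` returns the [raster_grid()].
#' @export
write_raster_tif <- function(raster, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  v <- raster$values
  ok <- !is.na(v)
  vmin <- if (any(ok)) min(v[ok]) else 0
  vmax <- if (any(ok)) max(v[ok]) else 1
  scale <- if (vmax > vmin) vmax - vmin else 1
  norm <- (v - vmin) / scale
  norm[!ok] <- 0
  arr <- array(c(norm, ok * 1), c(nrow(v), ncol(v), 2))
  tiff::writeTIFF(arr, path, bits.per.sample = 32L, reduce = FALSE)
  s <- raster$spec
  jsonlite::write_json(
    list(nrow = s$nrow, ncol = s$ncol, xmin = s$xmin, ymin = s$ymin,
         cellsize = s$cellsize, crs = s$crs, name = raster$name,
         vmin = vmin, vscale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster_tif
#' @export
read_raster_tif <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF import")
  # the value+mask channel pair has no photometric interpretation; libtiff
  # warns about the ExtraSamples tag on every read of such files
  arr <- suppressWarnings(tiff::readTIFF(path, as.is = FALSE))
  m <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- arr[, , 1] * m$vscale + m$vmin
  v[arr[, , 2] < 0.5] <- NA_real_
  raster_grid(v, grid_spec(m$nrow, m$ncol, m$xmin, m$ymin, m$cellsize, m$crs),
              name = m$name)
}

#' Write landscape polygons as GeoJSON
#'
#' Emits each rectangular landscape as a GeoJSON Polygon feature with its
#' `gradient_class` and `area_km2` (plus any median/direction columns)
#' as properties. Coordinates are in the grid's local equal-area frame.
#'
#' @param landscapes Landscape table from [gen_landscapes()].
#' @param path Output path (`.geojson`).
#' @export
write_landscapes_geojson <- function(landscapes, path) {
  props <- setdiff(names(landscapes),
                   c("xmin", "xmax", "ymin", "ymax", "row0", "row1", "col0", "col1"))
  features <- lapply(seq_len(nrow(landscapes)), function(i) {
    L <- landscapes[i, ]
    ring <- list(c(L$xmin, L$ymin), c(L$xmax, L$ymin), c(L$xmax, L$ymax),
                 c(L$xmin, L$ymax), c(L$xmin, L$ymin))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = as.list(L[props]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
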