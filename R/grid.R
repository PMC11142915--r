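#' Raster grid geometry
#'
#' Defines a regular raster grid in a local equal-area (metric) coordinate
#' frame: number of rows and columns, origin of the lower-left corner, and a
#' square cell size. Row 1 is the northernmost row, matching the usual
#' raster convention.
#'
#' @param nrow,ncol Grid dimensions (cells). Must be >= 1.
#' @param xmin,ymin Coordinates of the lower-left corner of the grid (m).
#' @param cellsize Cell edge length (m).
#' @param crs Free-text label of the coordinate reference frame. The default
#'   denotes a local Lambert-azimuthal-style equal-area plane in metres, so
#'   cell areas are exactly `cellsize^2`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nrow, ncol, xmin = 0, ymin = 0, cellsize = 1000,
                      crs = "local equal-area (m)") {
  if (nrow < 1 || ncol < 1) stop("grid dimensions must be positive")
  if (cellsize <= 0) stop("cellsize must be positive")
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         xmin = xmin, ymin = ymin, cellsize = cellsize,
         xmax = xmin + ncol * cellsize, ymax = ymin + nrow * cellsize,
         crs = crs),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, cell %g m, extent [%g, %g] x [%g, %g], crs: %s\n",
              x$nrow, x$ncol, x$cellsize, x$xmin, x$xmax, x$ymin, x$ymax, x$crs))
  invisible(x)
}

specs_equal <- function(a, b) {
  isTRUE(all.equal(a[c("nrow", "ncol", "xmin", "ymin", "cellsize")],
                   b[c("nrow", "ncol", "xmin", "ymin", "cellsize")]))
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!specs_equal(a, b))
    stop(sprintf("%s are not co-registered (differing grid geometry)", what))
  invisible(TRUE)
}

#' Single-layer raster
#'
#' A raster layer stored as a numeric matrix (row 1 = north) plus its
#' [grid_spec()]. `NA` encodes nodata throughout the package.
#'
#' @param values Numeric matrix with `spec$nrow` rows and `spec$ncol` columns.
#' @param spec A [grid_spec()].
#' @param name Optional layer name.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, spec, name = NULL) {
  values <- as.matrix(values)
  if (!identical(dim(values), c(spec$nrow, spec$ncol)))
    stop("values matrix does not match the grid dimensions")
  structure(list(values = values, spec = spec, name = name),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid%s> %d x %d cells, %d nodata, range [%s, %s]\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              nrow(v), ncol(v), sum(is.na(v)),
              format(suppressWarnings(min(v, na.rm = TRUE)), digits = 4),
              format(suppressWarnings(max(v, na.rm = TRUE)), digits = 4)))
  invisible(x)
}

#' Multi-layer raster stack
#'
#' A set of co-registered raster layers stored as a 3-D array
#' `[row, col, layer]`, tagged with the time period and, for future climate
#' stacks, the SSP scenario and GCM that produced it.
#'
#' @param values Numeric array `nrow x ncol x nlayer`.
#' @param layers Character vector of layer names (length `nlayer`).
#' @param spec A [grid_spec()].
#' @param period Period label (e.g. `"current"` or `"2081-2100"`).
#' @param ssp SSP label or `NA` for the current period.
#' @param gcm GCM label or `NA` for the current period.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(values, layers, spec, period = "current",
                         ssp = NA_character_, gcm = NA_character_) {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  if (dim(values)[3] != length(layers)) stop("layer names do not match array depth")
  if (!identical(dim(values)[1:2], c(spec$nrow, spec$ncol)))
    stop("array does not match the grid dimensions")
  dimnames(values)[[3]] <- layers
  structure(list(values = values, layers = layers, spec = spec,
                 period = period, ssp = ssp, gcm = gcm),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layers, %d x %d cells, period %s, ssp %s, gcm %s\n",
              length(x$layers), x$spec$nrow, x$spec$ncol,
              x$period, x$ssp, x$gcm))
  invisible(x)
}

#' Extract one layer of a stack as a raster_grid
#' @param stack A [raster_stack()].
#' @param layer Layer name or index.
#' @return A [raster_grid()].
#' @export
stack_layer <- function(stack, layer) {
  raster_grid(stack$values[, , layer], stack$spec,
              name = if (is.character(layer)) layer else stack$layers[layer])
}

#' Cell-centre coordinates of a grid
#' @param spec A [grid_spec()].
#' @return List with vectors `x` (length ncol, west to east) and `y`
#'   (length nrow, north to south), matching matrix row/column order.
#' @export
cell_centres <- function(spec) {
  list(x = spec$xmin + (seq_len(spec$ncol) - 0.5) * spec$cellsize,
       y = spec$ymax - (seq_len(spec$nrow) - 0.5) * spec$cellsize)
}

#' Map point coordinates to grid cell indices
#'
#' Cells are half-open: a point exactly on a shared vertical edge belongs to
#' the cell to its east, and on a shared horizontal edge to the cell to its
#' south. Points outside the grid extent get `NA` indices.
#'
#' @param spec A [grid_spec()].
#' @param x,y Point coordinates (same frame as the grid).
#' @return Data frame with integer columns `row` and `col` (`NA` outside).
#' @export
cell_index <- function(spec, x, y) {
  col <- floor((x - spec$xmin) / spec$cellsize) + 1
  row <- floor((spec$ymax - y) / spec$cellsize) + 1
  bad <- col < 1 | col > spec$ncol | row < 1 | row > spec$nrow
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}
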