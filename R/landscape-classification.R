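#' Zonal median of a raster over landscape polygons
#'
#' For each landscape, takes the median of the raster's non-nodata cells
#' whose centre falls inside the landscape rectangle (half-open
#' containment, consistent with the grid's cell ownership rule).
#' Landscapes with zero valid cells get a missing median.
#'
#' @param raster A [raster_grid()].
#' @param landscapes Landscape table from [gen_landscapes()] (rectangles
#'   with `xmin/xmax/ymin/ymax`).
#' @return Data frame with `id`, `median`, `n_valid` (valid cells), and
#'   `n_cells` (cells whose centre is inside).
#' @export
zonal_median <- function(raster, landscapes) {
  if (nrow(landscapes) == 0) stop("empty landscape set")
  cc <- cell_centres(raster$spec)
  X <- matrix(cc$x, raster$spec$nrow, raster$spec$ncol, byrow = TRUE)
  Y <- matrix(cc$y, raster$spec$nrow, raster$spec$ncol)
  out <- data.frame(id = landscapes$id, median = NA_real_,
                    n_valid = 0L, n_cells = 0L)
  for (i in seq_len(nrow(landscapes))) {
    L <- landscapes[i, ]
    inside <- X >= L$xmin & X < L$xmax & Y >= L$ymin & Y < L$ymax
    v <- raster$values[inside]
    out$n_cells[i] <- sum(inside)
    out$n_valid[i] <- sum(!is.na(v))
    if (out$n_valid[i] > 0) out$median[i] <- stats::median(v, na.rm = TRUE)
  }
  out
}

#' Classify a median change value as decreasing, stable, or increasing
#'
#' `"0"` (stable) iff `|value| <= stable_band` (boundary inclusive), `"+"`
#' above the band, `"-"` below it. Missing values stay unclassified (`NA`)
#' and are excluded from the 9-class table but counted separately.
#'
#' @param value Numeric vector of landscape median changes.
#' @param stable_band Half-width of the stable band, in the value's units
#'   (m of height difference, or % cover per year for TCC slopes).
#' @return Character vector with entries `"-"`, `"0"`, `"+"` or `NA`.
#' @export
classify_direction <- function(value, stable_band) {
  if (stable_band < 0) stop("stable_band must be >= 0")
  out <- rep(NA_character_, length(value))
  ok <- is.finite(value)
  out[ok & abs(value) <= stable_band] <- "0"
  out[ok & value > stable_band] <- "+"
  out[ok & value < -stable_band] <- "-"
  out
}

#' Cross-tabulate recent and future change directions into 9 classes
#'
#' Builds the 3 x 3 taxonomy of recent (tree canopy cover trend) by future
#' (potential canopy height change) directions, accumulating equal-area
#' landscape areas. Always emits all 9 rows, including zero-area classes.
#' Proportions are relative to the total domain area (the summed area of
#' every landscape, classified or not); landscapes missing either
#' direction are reported separately as unclassified area.
#'
#' @param landscapes Landscape table carrying `area_km2`,
#'   `recent_direction` and `future_direction` columns (`"-"`, `"0"`,
#'   `"+"`, or `NA`).
#' @param domain_area_km2 Denominator for proportions; defaults to the
#'   summed landscape area.
#' @return An object of class `change_class_table`: list with `table` (9
#'   rows: `recent`, `future`, `class`, `area_km2`, `proportion`, `n`),
#'   `unclassified_area_km2`, `unclassified_n`, `domain_area_km2`.
#' @export
change_matrix <- function(landscapes, domain_area_km2 = NULL) {
  need <- c("area_km2", "recent_direction", "future_direction")
  miss <- setdiff(need, names(landscapes))
  if (length(miss))
    stop("landscape table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(domain_area_km2)) domain_area_km2 <- sum(landscapes$area_km2)
  lv <- c("-", "0", "+")
  classified <- !is.na(landscapes$recent_direction) &
    !is.na(landscapes$future_direction)
  if (!any(classified)) stop("no landscape carries both change directions")
  g <- expand.grid(recent = lv, future = lv, stringsAsFactors = FALSE)
  g$class <- paste0(g$recent, "/", g$future)
  g$area_km2 <- 0
  g$n <- 0L
  cl <- landscapes[classified, ]
  for (i in seq_len(9)) {
    sel <- cl$recent_direction == g$recent[i] & cl$future_direction == g$future[i]
    g$area_km2[i] <- sum(cl$area_km2[sel])
    g$n[i] <- sum(sel)
  }
  g$proportion <- g$area_km2 / domain_area_km2
  structure(list(table = g,
                 unclassified_area_km2 = sum(landscapes$area_km2[!classified]),
                 unclassified_n = sum(!classified),
                 domain_area_km2 = domain_area_km2),
            class = "change_class_table")
}

#' @export
print.change_class_table <- function(x, ...) {
  cat("<change_class_table> recent x future change directions\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("unclassified: %.1f km2 (%d landscapes); domain: %.1f km2\n",
              x$unclassified_area_km2, x$unclassified_n, x$domain_area_km2))
  invisible(x)
}

#' Distribution summaries of landscape change by gradient class
#'
#' For each (gradient class, scenario key), summarises the distribution of
#' landscape median height differences in boxplot terms: median, lower and
#' upper hinges (Q1, Q3), IQR, and whiskers extending 1.5 x IQR beyond each
#' hinge. Quartiles use the default quantile definition (type 7). Classes
#' with no landscape are omitted with a warning.
#'
#' @param values Data frame in long form with columns `gradient_class`,
#'   `key`, `value` (one row per landscape x scenario key).
#' @return Data frame with `gradient_class`, `key`, `n`, `median`, `q1`,
#'   `q3`, `iqr`, `whisker_lo`, `whisker_hi`.
#' @export
summarize_by_gradient_class <- function(values) {
  need <- c("gradient_class", "key", "value")
  miss <- setdiff(need, names(values))
  if (length(miss))
    stop("values table is missing column(s): ", paste(miss, collapse = ", "))
  values <- values[is.finite(values$value), , drop = FALSE]
  empty <- setdiff(forest_gradient_classes(), unique(values$gradient_class))
  if (length(empty))
    warning("no landscapes in gradient class(es): ",
            paste(empty, collapse = ", "))
  groups <- unique(values[, c("gradient_class", "key")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    v <- values$value[values$gradient_class == groups$gradient_class[i] &
                        values$key == groups$key[i]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(gradient_class = groups$gradient_class[i], key = groups$key[i],
               n = length(v), median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
               whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[3] + 1.5 * iqr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
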