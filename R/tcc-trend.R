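#' Ordinary least squares trend of one pixel's annual cover series
#'
#' Simple linear regression of percent tree canopy cover on calendar year.
#' Years with nodata cover are omitted pairwise. The p-value is the
#' two-sided t-test of the year coefficient on `n - 2` degrees of freedom.
#' The slope is invariant to adding a constant to the cover or translating
#' the years, and scales linearly with the cover.
#'
#' @param values Numeric vector of percent cover, one entry per year
#'   (`NA` = nodata).
#' @param years Calendar years, same length as `values`.
#' @param min_obs Minimum number of finite observations required (default
#'   10); below it every output is `NA` except `n_obs`.
#' @return Named numeric vector `c(slope, p_value, n_obs)`; slope in % per
#'   year.
#' @export
pixel_trend <- function(values, years, min_obs = 10) {
  if (length(values) != length(years))
    stop("values and years differ in length")
  ok <- is.finite(values)
  n <- sum(ok)
  if (n < max(min_obs, 3)) return(c(slope = NA_real_, p_value = NA_real_, n_obs = n))
  x <- years[ok]; y <- values[ok]
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx == 0) return(c(slope = NA_real_, p_value = NA_real_, n_obs = n))
  slope <- sum((x - xb) * (y - yb)) / sxx
  resid <- y - yb - slope * (x - xb)
  s2 <- sum(resid^2) / (n - 2)
  if (s2 <= 0) {
    p <- if (slope == 0) 1 else 0  # perfectly collinear series
  } else {
    tstat <- slope / sqrt(s2 / sxx)
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  c(slope = slope, p_value = p, n_obs = n)
}

#' Per-pixel trend map of an annual tree-canopy-cover series
#'
#' Applies [pixel_trend()] at every pixel of an annual raster series
#' (vectorised), returning slope, p-value and observation-count rasters.
#' Pixels with fewer than `min_obs` finite years are masked.
#'
#' @param series A [raster_stack()] with one layer per year (layer names
#'   are the years) or a list with elements `tcc` and `years` as returned
#'   by [gen_tcc_series()].
#' @param years Calendar years matching the layers (taken from layer names
#'   when omitted).
#' @param min_obs Minimum finite years per pixel (default 10).
#' @return List with `slope`, `p_value`, `n_obs` ([raster_grid()]s) and
#'   `n_masked`, the number of pixels masked for insufficient data.
#' @export
trend_map <- function(series, years = NULL, min_obs = 10) {
  if (is.list(series) && !inherits(series, "raster_stack") &&
      !is.null(series$tcc)) {
    if (is.null(years)) years <- series$years
    series <- series$tcc
  }
  if (is.null(years)) years <- as.numeric(series$layers)
  if (length(years) != length(series$layers))
    stop("years do not match the number of annual layers")
  if (length(years) < 3) stop("at least 3 years are required")
  spec <- series$spec
  np <- spec$nrow * spec$ncol
  ny <- length(years)
  Y <- series$values
  dim(Y) <- c(np, ny)
  M <- is.finite(Y)
  Y0 <- ifelse(M, Y, 0)
  n <- rowSums(M)
  yrs <- matrix(years, np, ny, byrow = TRUE)
  xs <- rowSums(M * yrs)
  xb <- xs / n
  sxx <- rowSums(M * (yrs - xb)^2)
  yb <- rowSums(Y0) / n
  sxy <- rowSums(M * (yrs - xb) * (Y0 - M * yb))
  valid <- n >= max(min_obs, 3) & sxx > 0
  slope <- ifelse(valid, sxy / sxx, NA_real_)
  resid2 <- rowSums(M * (Y0 - M * yb - ifelse(is.na(slope), 0, slope) * (yrs - xb))^2)
  s2 <- resid2 / pmax(n - 2, 1)
  p <- rep(NA_real_, np)
  pos <- which(valid & s2 > 0)
  if (length(pos)) {
    tstat <- slope[pos] / sqrt(s2[pos] / sxx[pos])
    p[pos] <- 2 * stats::pt(-abs(tstat), df = n[pos] - 2)
  }
  exact <- which(valid & s2 <= 0)  # noiseless series
  p[exact] <- ifelse(slope[exact] == 0, 1, 0)
  as_grid <- function(v, nm)
    raster_grid(matrix(v, spec$nrow, spec$ncol), spec, name = nm)
  list(slope = as_grid(slope, "tcc_slope"),
       p_value = as_grid(p, "tcc_p_value"),
       n_obs = as_grid(n, "tcc_n_obs"),
       n_masked = sum(!valid))
}
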