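#' Predictor variable names
#'
#' The height model uses 22 predictors: 3 soil variables (permafrost
#' probability in \[0, 1\], depth to bedrock in m, organic carbon density at
#' 0 m depth) held constant through time, and the 19 bioclimatic variables
#' derived from monthly temperature (deg C) and precipitation (mm).
#'
#' @return Character vector of length 3 (`soil_predictor_names`), 19
#'   (`bioclim_predictor_names`) or 22 (`predictor_names`).
#' @export
predictor_names <- function() c(soil_predictor_names(), bioclim_predictor_names())

#' @rdname predictor_names
#' @export
soil_predictor_names <- function() {
  c("permafrost_probability", "depth_to_bedrock", "organic_carbon_density")
}

#' @rdname predictor_names
#' @export
bioclim_predictor_names <- function() {
  c("bio01_annual_mean_temperature", "bio02_mean_diurnal_range",
    "bio03_isothermality", "bio04_temperature_seasonality",
    "bio05_max_temp_warmest_month", "bio06_min_temp_coldest_month",
    "bio07_temperature_annual_range", "bio08_mean_temp_wettest_quarter",
    "bio09_mean_temp_driest_quarter", "bio10_mean_temp_warmest_quarter",
    "bio11_mean_temp_coldest_quarter", "bio12_annual_precipitation",
    "bio13_precip_wettest_month", "bio14_precip_driest_month",
    "bio15_precip_seasonality", "bio16_precip_wettest_quarter",
    "bio17_precip_driest_quarter", "bio18_precip_warmest_quarter",
    "bio19_precip_coldest_quarter")
}

# temperature-family layers shifted additively under future warming
temp_shift_layers <- function() {
  c("bio01_annual_mean_temperature", "bio05_max_temp_warmest_month",
    "bio06_min_temp_coldest_month", "bio08_mean_temp_wettest_quarter",
    "bio09_mean_temp_driest_quarter", "bio10_mean_temp_warmest_quarter",
    "bio11_mean_temp_coldest_quarter")
}

precip_scale_layers <- function() {
  c("bio12_annual_precipitation", "bio13_precip_wettest_month",
    "bio14_precip_driest_month", "bio16_precip_wettest_quarter",
    "bio17_precip_driest_quarter", "bio18_precip_warmest_quarter",
    "bio19_precip_coldest_quarter")
}

#' Forest gradient class vocabulary
#'
#' The six landscape classes spanning the latitudinal forest gradient, from
#' treeless tundra through the taiga-tundra ecotone (TTE) to interior boreal
#' forest, ordered north to south.
#'
#' @return Character vector of length 6.
#' @export
forest_gradient_classes <- function() {
  c("Non-forest (tundra)", "TTE (sparse)", "TTE (diffuse)", "TTE (abrupt)",
    "TTE (forest dominant)", "Boreal Forest (taiga)")
}

#' Classes counted as transitional (TTE)
#' @return Character vector of the 4 TTE class labels.
#' @export
tte_classes <- function() forest_gradient_classes()[2:5]

# ---------------------------------------------------------------------------
# Seed substreams: every stage draws from its own named stream derived from
# the master seed, so adding draws to one stage never perturbs another.

substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 1000000007
  as.integer((abs(as.numeric(seed)) * 69069 + h) %% 2147483629)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Smooth mean-zero random field (unit-ish variance) as a sum of random
# cosine modes; wavelength controlled in cell units.
smooth_field <- function(nrow, ncol, n_modes = 12, corr_length = 12) {
  f <- matrix(0, nrow, ncol)
  ri <- row(f); ci <- col(f)
  for (j in seq_len(n_modes)) {
    u <- stats::rnorm(1, sd = 1 / corr_length)
    v <- stats::rnorm(1, sd = 1 / corr_length)
    ph <- stats::runif(1, 0, 2 * pi)
    a <- stats::rnorm(1)
    f <- f + a * cos(2 * pi * (u * ri + v * ci) + ph)
  }
  f / sqrt(n_modes / 2)
}

# ---------------------------------------------------------------------------

#' Configuration of the synthetic study system
#'
#' Collects every free parameter of the synthetic-data generator: the grid,
#' the scenario structure (GCMs, 4 SSPs ordered by severity, 4 future
#' 20-year periods), the true climate-to-height law, planted tree-canopy-
#' cover trends, noise levels, and the planted failure fractions for the
#' seven lidar quality predicates. A fixed seed makes every generated
#' product bit-for-bit reproducible; each generator stage draws from its own
#' named substream of the seed.
#'
#' @param grid_nrow,grid_ncol Grid dimensions (cells); row 1 is north.
#' @param cellsize Cell size (m); the default 1000 matches 1 km gridding.
#' @param years Calendar years of the annual tree-canopy-cover series.
#' @param n_points Number of synthetic lidar segment observations.
#' @param seed Master integer seed.
#' @param gcm_list Labels of the global climate models (>= 1).
#' @param ssp_list 4 SSP labels ordered by increasing severity.
#' @param period_list 4 future 20-year period labels ordered in time.
#' @param height_law_params True climate-height law coefficients: `hmax`
#'   (asymptotic height, m), `k` (logistic steepness, per deg C), `t0`
#'   (temperature of half-maximal height, deg C), `b_precip` (m per mm of
#'   wettest-quarter precipitation), `c_permafrost` (height penalty, m, at
#'   permafrost probability 1).
#' @param tcc_trend_field_params Planted TCC slope field: `slope_north` and
#'   `slope_south` (%/yr at the north and south edges, linearly
#'   interpolated), `sd` (pixel-level slope spread, %/yr), `intercept_north`
#'   and `intercept_south` (% cover at the series start).
#' @param noise_sd_height Lidar height observation noise sd (m).
#' @param noise_sd_tcc Annual TCC observation noise sd (% cover).
#' @param fail_fractions Named fractions of points planted to fail each of
#'   the seven quality predicates (`weak_beam`, `snow`, `cloud`, `solar`,
#'   `rh98_range`, `height_diff`, `geoloc`).
#' @param flag_fraction Fraction of points carrying the canopy-height flag
#'   that zeroes assumed-erroneous heights.
#' @param warming Future warming law: `w0` (deg C of annual-mean-temperature
#'   increase per unit severity-rank x period-index) and `gcm_amp`
#'   (amplitude of the per-GCM smooth perturbation field, deg C, kept below
#'   `0.75 * w0` so warming stays monotone in rank and period at every
#'   pixel), plus `precip_rate` (fractional precipitation increase per unit
#'   rank x period).
#' @param temp_range Domain temperature span `c(north, south)` (deg C) of
#'   current annual mean temperature.
#' @return An object of class `gen_config` (a validated list).
#' @export
gen_config <- function(grid_nrow = 50, grid_ncol = 50, cellsize = 1000,
                       years = 1984:2020, n_points = 10000, seed = 1,
                       gcm_list = c("GCM-A", "GCM-B", "GCM-C"),
                       ssp_list = c("SSP126", "SSP245", "SSP370", "SSP585"),
                       period_list = c("2021-2040", "2041-2060",
                                       "2061-2080", "2081-2100"),
                       height_law_params = list(hmax = 20, k = 0.45, t0 = -2,
                                                b_precip = 0.004,
                                                c_permafrost = 3),
                       tcc_trend_field_params = list(slope_north = 0.3,
                                                     slope_south = -0.05,
                                                     sd = 0.05,
                                                     intercept_north = 8,
                                                     intercept_south = 60),
                       noise_sd_height = 0.5, noise_sd_tcc = 2,
                       fail_fractions = list(weak_beam = 0.10, snow = 0.05,
                                             cloud = 0.05, solar = 0.05,
                                             rh98_range = 0.02,
                                             height_diff = 0.02,
                                             geoloc = 0.02),
                       flag_fraction = 0.08,
                       warming = list(w0 = 0.4, gcm_amp = 0.1,
                                      precip_rate = 0.012),
                       temp_range = c(-10, 4)) {
  if (length(ssp_list) != 4L) stop("ssp_list must have length 4")
  if (length(period_list) != 4L) stop("period_list must have length 4")
  if (length(gcm_list) < 1L) stop("at least 1 GCM is required")
  if (grid_nrow < 1 || grid_ncol < 1) stop("grid dimensions must be positive")
  if (noise_sd_height < 0 || noise_sd_tcc < 0) stop("noise sds must be >= 0")
  if (any(unlist(fail_fractions) < 0) || any(unlist(fail_fractions) > 1))
    stop("fail_fractions must lie in [0, 1]")
  if (warming$gcm_amp > 0.75 * warming$w0)
    stop("warming$gcm_amp must be <= 0.75 * warming$w0 to keep warming monotone")
  cfg <- list(grid_nrow = as.integer(grid_nrow), grid_ncol = as.integer(grid_ncol),
              cellsize = cellsize, years = as.integer(years),
              n_points = as.integer(n_points), seed = as.integer(seed),
              gcm_list = gcm_list, ssp_list = ssp_list, period_list = period_list,
              height_law_params = height_law_params,
              tcc_trend_field_params = tcc_trend_field_params,
              noise_sd_height = noise_sd_height, noise_sd_tcc = noise_sd_tcc,
              fail_fractions = fail_fractions, flag_fraction = flag_fraction,
              warming = warming, temp_range = temp_range)
  cfg$spec <- grid_spec(grid_nrow, grid_ncol, cellsize = cellsize)
  class(cfg) <- "gen_config"
  cfg
}

#' True climate-to-height law of the synthetic system
#'
#' Canopy height saturates logistically with annual mean temperature
#' (temperature dominates the variance), increases linearly with
#' wettest-quarter precipitation, and is penalised by permafrost
#' probability; negative values are clipped to 0.
#'
#' @param tmean Annual mean temperature (deg C), vector or matrix.
#' @param precip_wet Precipitation of the wettest quarter (mm).
#' @param permafrost Permafrost probability in \[0, 1\].
#' @param params Coefficient list, see [gen_config()].
#' @return Heights (m), same shape as the inputs.
#' @export
height_law <- function(tmean, precip_wet, permafrost,
                       params = gen_config()$height_law_params) {
  h <- params$hmax * stats::plogis(params$k * (tmean - params$t0)) +
    params$b_precip * precip_wet - params$c_permafrost * permafrost
  pmax(h, 0)
}

#' Generate the current and future covariate stacks
#'
#' Builds the current 22-layer covariate stack (3 soil + 19 bioclim) and one
#' stack per (GCM, SSP, period). Soil layers are identical across every
#' period and scenario. Warming is `(w0 + g_gcm(pixel)) * rank(ssp) *
#' index(period)` added to the temperature-family layers, with `g_gcm` a
#' smooth per-GCM field bounded below `w0`, so at every pixel annual mean
#' temperature increases strictly with period index and with SSP severity
#' rank; precipitation layers scale up analogously.
#'
#' @param config A [gen_config()].
#' @return List with `current` (a [raster_stack()]), `future` (named list of
#'   stacks keyed `"gcm|ssp|period"`), `true_height` (a [raster_grid()] of
#'   the noise-free law applied to the current stack), and `meta` (a data
#'   frame of the future stack keys).
#' @export
gen_covariate_stacks <- function(config) {
  spec <- config$spec
  nr <- spec$nrow; nc <- spec$ncol
  layers <- predictor_names()

  cur <- with_substream(config$seed, "covariates", {
    lat <- (row(matrix(0, nr, nc)) - 1) / max(nr - 1, 1)  # 0 north -> 1 south
    tn <- config$temp_range[1]; ts <- config$temp_range[2]
    tmean <- tn + (ts - tn) * lat + 1.5 * smooth_field(nr, nc)
    precip <- pmax(450 + 120 * smooth_field(nr, nc), 60)

    a <- array(NA_real_, c(nr, nc, length(layers)), dimnames = list(NULL, NULL, layers))
    a[, , "permafrost_probability"] <-
      pmin(pmax(stats::plogis(-(tmean + 2) / 1.5) + 0.05 * smooth_field(nr, nc), 0), 1)
    a[, , "depth_to_bedrock"] <- pmax(8 + 4 * smooth_field(nr, nc), 0.5)
    a[, , "organic_carbon_density"] <- pmax(35 + 12 * smooth_field(nr, nc), 1)

    a[, , "bio01_annual_mean_temperature"] <- tmean
    a[, , "bio02_mean_diurnal_range"] <- pmax(9 + 1.5 * smooth_field(nr, nc), 2)
    a[, , "bio03_isothermality"] <- pmax(22 + 3 * smooth_field(nr, nc), 5)
    a[, , "bio04_temperature_seasonality"] <- pmax(1200 + 120 * smooth_field(nr, nc), 300)
    a[, , "bio05_max_temp_warmest_month"] <- tmean + 18 + 2 * smooth_field(nr, nc)
    a[, , "bio06_min_temp_coldest_month"] <- tmean - 24 + 2 * smooth_field(nr, nc)
    a[, , "bio07_temperature_annual_range"] <-
      a[, , "bio05_max_temp_warmest_month"] - a[, , "bio06_min_temp_coldest_month"]
    a[, , "bio08_mean_temp_wettest_quarter"] <- tmean + 4 + 2 * smooth_field(nr, nc)
    a[, , "bio09_mean_temp_driest_quarter"] <- tmean - 3 + 2 * smooth_field(nr, nc)
    a[, , "bio10_mean_temp_warmest_quarter"] <- tmean + 11 + 1.5 * smooth_field(nr, nc)
    a[, , "bio11_mean_temp_coldest_quarter"] <- tmean - 14 + 1.5 * smooth_field(nr, nc)
    a[, , "bio12_annual_precipitation"] <- precip
    a[, , "bio13_precip_wettest_month"] <- pmax(0.18 * precip + 10 * smooth_field(nr, nc), 5)
    a[, , "bio14_precip_driest_month"] <- pmax(0.04 * precip + 4 * smooth_field(nr, nc), 0)
    a[, , "bio15_precip_seasonality"] <- pmax(45 + 8 * smooth_field(nr, nc), 5)
    a[, , "bio16_precip_wettest_quarter"] <- pmax(0.45 * precip + 25 * smooth_field(nr, nc), 10)
    a[, , "bio17_precip_driest_quarter"] <- pmax(0.14 * precip + 8 * smooth_field(nr, nc), 2)
    a[, , "bio18_precip_warmest_quarter"] <- pmax(0.40 * precip + 20 * smooth_field(nr, nc), 5)
    a[, , "bio19_precip_coldest_quarter"] <- pmax(0.18 * precip + 10 * smooth_field(nr, nc), 2)
    a
  })
  current <- raster_stack(cur, layers, spec, period = "current")

  w0 <- config$warming$w0
  amp <- config$warming$gcm_amp
  precip_rate <- config$warming$precip_rate
  tl <- temp_shift_layers()
  pl <- precip_scale_layers()

  future <- list()
  meta <- list()
  for (g in config$gcm_list) {
    gf <- with_substream(config$seed, paste0("gcm:", g), smooth_field(nr, nc))
    gfield <- pmin(pmax(amp * gf, -0.75 * w0), 0.75 * w0)
    pfield <- pmin(pmax(0.3 * gf, -0.9), 0.9)
    for (si in seq_along(config$ssp_list)) {
      for (pi in seq_along(config$period_list)) {
        warm <- (w0 + gfield) * si * pi
        pscale <- 1 + precip_rate * (1 + 0.3 * pfield) * si * pi
        a <- cur
        for (ly in tl) a[, , ly] <- a[, , ly] + warm
        a[, , "bio07_temperature_annual_range"] <-
          a[, , "bio05_max_temp_warmest_month"] - a[, , "bio06_min_temp_coldest_month"]
        for (ly in pl) a[, , ly] <- a[, , ly] * pscale
        key <- scenario_gcm_key(g, config$ssp_list[si], config$period_list[pi])
        future[[key]] <- raster_stack(a, layers, spec,
                                      period = config$period_list[pi],
                                      ssp = config$ssp_list[si], gcm = g)
        meta[[length(meta) + 1L]] <- data.frame(
          gcm = g, ssp = config$ssp_list[si], period = config$period_list[pi],
          ssp_rank = si, period_index = pi, key = key,
          stringsAsFactors = FALSE)
      }
    }
  }

  true_height <- raster_grid(
    height_law(cur[, , "bio01_annual_mean_temperature"],
               cur[, , "bio16_precip_wettest_quarter"],
               cur[, , "permafrost_probability"],
               config$height_law_params),
    spec, name = "true_height")

  list(current = current, future = future, true_height = true_height,
       meta = do.call(rbind, meta))
}

#' Key identifying a (GCM, SSP, period) stack
#' @param gcm,ssp,period Labels.
#' @return Character key `"gcm|ssp|period"`.
#' @export
scenario_gcm_key <- function(gcm, ssp, period) paste(gcm, ssp, period, sep = "|")

# sample a stack layer at point coordinates (cell lookup)
sample_stack <- function(stack, x, y) {
  idx <- cell_index(stack$spec, x, y)
  out <- matrix(NA_real_, length(x), length(stack$layers),
                dimnames = list(NULL, stack$layers))
  ok <- !is.na(idx$row)
  flat <- cbind(idx$row[ok], idx$col[ok])
  for (j in seq_along(stack$layers)) {
    lay <- stack$values[, , j]
    out[ok, j] <- lay[flat]
  }
  out
}

#' Generate synthetic lidar canopy-height observations
#'
#' Emits ATL08-style 20 m segment observations: RH98 equals the true height
#' law evaluated at the point's grid cell plus Gaussian noise (clipped at
#' 0), and the quality attributes are drawn so that a configured fraction of
#' points fails each of the seven filtering predicates. Failures of the
#' RH98-validity predicate are planted by replacing the height with a value
#' above the 30 m validity bound. The returned truth table records, for
#' every point, the Bernoulli pass/fail draw of every predicate.
#'
#' @param config A [gen_config()].
#' @param current_stack The current covariate [raster_stack()].
#' @return List with `points` (data frame with fields `lon`, `lat`, `rh98`,
#'   `beam`, `snow_flag`, `cloud_flag`, `solar_elevation`,
#'   `landcover_class`, `height_diff_ref`, `geoloc_error`,
#'   `height_flagged`) and `truth` (data frame of `pass_*` logicals plus
#'   `all_pass` and the noise-free `true_height`).
#' @export
gen_canopy_points <- function(config, current_stack) {
  n <- config$n_points
  if (n <= 0) stop("n_points must be positive")
  spec <- current_stack$spec
  ff <- config$fail_fractions

  with_substream(config$seed, "points", {
    x <- stats::runif(n, spec$xmin, spec$xmax - 1e-9)
    y <- stats::runif(n, spec$ymin + 1e-9, spec$ymax)
    cov <- sample_stack(current_stack, x, y)
    true_h <- height_law(cov[, "bio01_annual_mean_temperature"],
                         cov[, "bio16_precip_wettest_quarter"],
                         cov[, "permafrost_probability"],
                         config$height_law_params)
    rh98 <- pmax(true_h + stats::rnorm(n, sd = config$noise_sd_height), 0)

    fail <- function(p) stats::runif(n) < p
    f_beam <- fail(ff$weak_beam)
    f_snow <- fail(ff$snow)
    f_cloud <- fail(ff$cloud)
    f_solar <- fail(ff$solar)
    f_rh98 <- fail(ff$rh98_range)
    f_hdiff <- fail(ff$height_diff)
    f_geo <- fail(ff$geoloc)

    rh98[f_rh98] <- stats::runif(sum(f_rh98), 30.5, 45)
    solar <- ifelse(f_solar, stats::runif(n, 5.5, 40), stats::runif(n, -30, 4.5))
    hdiff <- ifelse(f_hdiff, stats::runif(n, 25.5, 60), stats::runif(n, 0, 24.5))
    geoe <- ifelse(f_geo, stats::runif(n, 2.6, 8), stats::runif(n, 0, 2.4))
    lc <- sample(c("evergreen needleleaf forest", "woodland", "shrubland",
                   "tundra", "barren"), n, replace = TRUE,
                 prob = c(0.35, 0.25, 0.2, 0.15, 0.05))
    flagged <- fail(config$flag_fraction)

    points <- data.frame(
      lon = x, lat = y, rh98 = rh98,
      beam = ifelse(f_beam, "weak", "strong"),
      snow_flag = f_snow, cloud_flag = f_cloud,
      solar_elevation = solar, landcover_class = lc,
      height_diff_ref = hdiff, geoloc_error = geoe,
      height_flagged = flagged, stringsAsFactors = FALSE)
    truth <- data.frame(
      pass_strong_beam = !f_beam, pass_snow_free = !f_snow,
      pass_cloud_free = !f_cloud, pass_solar = !f_solar,
      pass_rh98_valid = !f_rh98, pass_height_diff = !f_hdiff,
      pass_geoloc = !f_geo, true_height = true_h)
    truth$all_pass <- with(truth, pass_strong_beam & pass_snow_free &
                             pass_cloud_free & pass_solar & pass_rh98_valid &
                             pass_height_diff & pass_geoloc)
    list(points = points, truth = truth)
  })
}

#' Generate an annual tree-canopy-cover raster series with planted trends
#'
#' Per pixel, TCC follows `intercept + slope * (year - years[1]) + noise`,
#' clipped to \[0, 100\]. The planted slope field interpolates linearly from
#' `slope_north` at the north edge to `slope_south` at the south edge plus
#' independent pixel-level spread, emulating the observed concentration of
#' positive canopy-cover trends at the cold northern margin.
#'
#' @param config A [gen_config()].
#' @return List with `tcc` (a [raster_stack()] with one layer per year,
#'   layer names = years), `years`, `true_slope` and `true_intercept`
#'   ([raster_grid()]s).
#' @export
gen_tcc_series <- function(config) {
  years <- config$years
  if (length(years) < 3) stop("at least 3 years are required")
  spec <- config$spec
  nr <- spec$nrow; nc <- spec$ncol
  p <- config$tcc_trend_field_params

  with_substream(config$seed, "tcc", {
    lat <- (row(matrix(0, nr, nc)) - 1) / max(nr - 1, 1)  # 0 north -> 1 south
    slope <- p$slope_north + (p$slope_south - p$slope_north) * lat +
      matrix(stats::rnorm(nr * nc, sd = p$sd), nr, nc)
    intercept <- p$intercept_north + (p$intercept_south - p$intercept_north) * lat
    a <- array(NA_real_, c(nr, nc, length(years)),
               dimnames = list(NULL, NULL, as.character(years)))
    for (i in seq_along(years)) {
      v <- intercept + slope * (years[i] - years[1])
      if (config$noise_sd_tcc > 0)
        v <- v + matrix(stats::rnorm(nr * nc, sd = config$noise_sd_tcc), nr, nc)
      a[, , i] <- pmin(pmax(v, 0), 100)
    }
    list(tcc = raster_stack(a, as.character(years), spec, period = "tcc"),
         years = years,
         true_slope = raster_grid(slope, spec, name = "true_slope"),
         true_intercept = raster_grid(intercept, spec, name = "true_intercept"))
  })
}

#' Generate landscape polygons tiling the grid
#'
#' Partitions the grid into rectangular catchment-like landscapes arranged
#' in `n_tiles_y` latitudinal bands of `n_tiles_x` tiles each. Each band
#' carries one forest gradient class, ordered north to south through the
#' 6-class vocabulary (tundra at the top row of bands, interior boreal at
#' the bottom), mirroring the latitudinal forest gradient. Tiles are
#' half-open rectangles that cover every grid cell exactly once; areas are
#' exact in the grid's equal-area frame.
#'
#' @param config A [gen_config()].
#' @param n_tiles_x,n_tiles_y Tiling of the domain (default 5 x 6 = 30
#'   landscapes, one class per band).
#' @return Data frame with one row per landscape: `id`, `gradient_class`,
#'   cell index ranges `row0/row1/col0/col1`, rectangle coordinates
#'   `xmin/xmax/ymin/ymax` (m), `n_cells` and `area_km2`.
#' @export
gen_landscapes <- function(config, n_tiles_x = 5, n_tiles_y = 6) {
  spec <- config$spec
  if (n_tiles_x * n_tiles_y > spec$nrow * spec$ncol)
    stop("requested more landscapes than grid cells")
  if (n_tiles_y > spec$nrow || n_tiles_x > spec$ncol)
    stop("more tiles than cells along one axis")
  row_breaks <- round(seq(0, spec$nrow, length.out = n_tiles_y + 1))
  col_breaks <- round(seq(0, spec$ncol, length.out = n_tiles_x + 1))
  classes <- forest_gradient_classes()
  band_class <- classes[round(seq(1, 6, length.out = n_tiles_y))]

  rows <- list()
  id <- 0L
  for (by in seq_len(n_tiles_y)) {
    r0 <- row_breaks[by] + 1L; r1 <- row_breaks[by + 1]
    for (bx in seq_len(n_tiles_x)) {
      c0 <- col_breaks[bx] + 1L; c1 <- col_breaks[bx + 1]
      id <- id + 1L
      ncell <- (r1 - r0 + 1L) * (c1 - c0 + 1L)
      rows[[id]] <- data.frame(
        id = id, gradient_class = band_class[by],
        row0 = r0, row1 = r1, col0 = c0, col1 = c1,
        xmin = spec$xmin + (c0 - 1) * spec$cellsize,
        xmax = spec$xmin + c1 * spec$cellsize,
        ymin = spec$ymax - r1 * spec$cellsize,
        ymax = spec$ymax - (r0 - 1) * spec$cellsize,
        n_cells = ncell,
        area_km2 = ncell * (spec$cellsize / 1000)^2,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  out
}
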