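test_that("config invariants are enforced", {
  expect_error(gen_config(ssp_list = c("a", "b")), "length 4")
  expect_error(gen_config(period_list = c("a")), "length 4")
  expect_error(gen_config(gcm_list = character(0)), "GCM")
  expect_error(gen_config(grid_nrow = 0), "positive")
  expect_error(gen_config(noise_sd_height = -1), ">= 0")
})

test_that("covariate stacks have the right count, layers, and constant soils", {
  cfg <- tiny_config()
  st <- gen_covariate_stacks(cfg)
  # 2 GCMs x 4 SSPs x 4 periods + 1 current
  expect_length(st$future, 32)
  expect_equal(length(st$current$layers), 22)
  for (s in st$future) expect_equal(length(s$layers), 22)
  # soil layers held constant across the temporal domain
  for (ly in soil_predictor_names()) {
    for (s in st$future)
      expect_identical(s$values[, , ly], st$current$values[, , ly])
  }
})

test_that("warming is everywhere positive and monotone in severity and period", {
  cfg <- gen_config(grid_nrow = 15, grid_ncol = 15, seed = 7,
                    gcm_list = c("GCM-A", "GCM-B"))
  st <- gen_covariate_stacks(cfg)
  tl <- "bio01_annual_mean_temperature"
  for (g in cfg$gcm_list) {
    hot <- st$future[[scenario_gcm_key(g, cfg$ssp_list[4], cfg$period_list[4])]]
    cold <- st$future[[scenario_gcm_key(g, cfg$ssp_list[1], cfg$period_list[1])]]
    expect_true(all(hot$values[, , tl] - cold$values[, , tl] > 0))
    # strictly increasing mean temperature with period index for each SSP
    for (ssp in cfg$ssp_list) {
      means <- sapply(cfg$period_list, function(p)
        mean(st$future[[scenario_gcm_key(g, ssp, p)]]$values[, , tl]))
      expect_true(all(diff(means) > 0))
    }
    # and with SSP severity rank at every pixel, for each period
    for (p in cfg$period_list) {
      for (i in 1:3) {
        lo <- st$future[[scenario_gcm_key(g, cfg$ssp_list[i], p)]]$values[, , tl]
        hi <- st$future[[scenario_gcm_key(g, cfg$ssp_list[i + 1], p)]]$values[, , tl]
        expect_true(all(hi - lo > 0))
      }
    }
  }
})

test_that("identical configs give bit-identical outputs across all generators", {
  cfg <- tiny_config(seed = 13)
  a <- gen_covariate_stacks(cfg)
  b <- gen_covariate_stacks(cfg)
  expect_identical(a, b)
  expect_identical(gen_canopy_points(cfg, a$current),
                   gen_canopy_points(cfg, b$current))
  expect_identical(gen_tcc_series(cfg), gen_tcc_series(cfg))
  expect_identical(gen_landscapes(cfg), gen_landscapes(cfg))
})

test_that("generator substreams are independent across stages", {
  cfg <- tiny_config(seed = 5)
  st1 <- gen_covariate_stacks(cfg)
  pts_alone <- gen_canopy_points(cfg, st1$current)
  # interleaving another stage's draws must not perturb the points
  invisible(gen_tcc_series(cfg))
  pts_again <- gen_canopy_points(cfg, st1$current)
  expect_identical(pts_alone, pts_again)
})

test_that("points carry every predicate field and honest truth vectors", {
  cfg <- tiny_config(seed = 3)
  st <- gen_covariate_stacks(cfg)
  pts <- gen_canopy_points(cfg, st$current)
  expect_true(all(c("lon", "lat", "rh98", "beam", "snow_flag", "cloud_flag",
                    "solar_elevation", "landcover_class", "height_diff_ref",
                    "geoloc_error", "height_flagged") %in% names(pts$points)))
  expect_equal(nrow(pts$truth), cfg$n_points)
  # truth draws agree with the emitted attributes, predicate by predicate
  expect_identical(pts$truth$pass_strong_beam, pts$points$beam == "strong")
  expect_identical(pts$truth$pass_snow_free, !pts$points$snow_flag)
  expect_identical(pts$truth$pass_cloud_free, !pts$points$cloud_flag)
  expect_identical(pts$truth$pass_solar, pts$points$solar_elevation < 5)
  expect_identical(pts$truth$pass_rh98_valid, pts$points$rh98 <= 30)
  expect_identical(pts$truth$pass_height_diff, pts$points$height_diff_ref < 25)
  expect_identical(pts$truth$pass_geoloc, pts$points$geoloc_error < 2.5)
})

test_that("all-pass composition and the noiseless height limit hold", {
  cfg <- tiny_config(seed = 2, noise_sd_height = 0,
                     fail_fractions = all_pass_fractions())
  st <- gen_covariate_stacks(cfg)
  pts <- gen_canopy_points(cfg, st$current)
  expect_true(all(pts$truth$all_pass))
  expect_equal(pts$points$rh98, pts$truth$true_height)
})

test_that("planted weak-beam fraction is recountable from the emitted table", {
  cfg <- gen_config(grid_nrow = 20, grid_ncol = 20, n_points = 10000,
                    seed = 11, fail_fractions = list(
                      weak_beam = 0.10, snow = 0, cloud = 0, solar = 0,
                      rh98_range = 0, height_diff = 0, geoloc = 0))
  st <- gen_covariate_stacks(cfg)
  pts <- gen_canopy_points(cfg, st$current)
  n_weak <- sum(pts$points$beam == "weak")
  expect_equal(n_weak, sum(!pts$truth$pass_strong_beam))
  # the drawn fraction is near its target
  expect_gt(n_weak / 10000, 0.08)
  expect_lt(n_weak / 10000, 0.12)
})

test_that("tcc series follows the planted linear law", {
  cfg <- tiny_config(
    years = 1984:2000, noise_sd_tcc = 0,
    tcc_trend_field_params = list(slope_north = 0.5, slope_south = 0.5,
                                  sd = 0, intercept_north = 10,
                                  intercept_south = 10))
  ser <- gen_tcc_series(cfg)
  # year-10 value: 10 + 0.5 * 10 = 15 at every pixel
  expect_equal(unname(ser$tcc$values[, , "1994"]),
               matrix(15, 20, 20))
  # zero slope, zero noise: all years identical
  cfg0 <- tiny_config(
    years = 1984:1990, noise_sd_tcc = 0,
    tcc_trend_field_params = list(slope_north = 0, slope_south = 0, sd = 0,
                                  intercept_north = 30, intercept_south = 30))
  ser0 <- gen_tcc_series(cfg0)
  for (i in 2:7)
    expect_identical(ser0$tcc$values[, , i], ser0$tcc$values[, , 1])
})

test_that("tcc values are clipped to [0, 100] under noise", {
  cfg <- tiny_config(noise_sd_tcc = 40)
  ser <- gen_tcc_series(cfg)
  expect_true(all(ser$tcc$values >= 0 & ser$tcc$values <= 100))
})

test_that("landscape tiling conserves the domain exactly", {
  cfg <- tiny_config()
  ls <- gen_landscapes(cfg)
  domain_km2 <- cfg$spec$nrow * cfg$spec$ncol * (cfg$spec$cellsize / 1000)^2
  expect_lt(abs(sum(ls$area_km2) - domain_km2) / domain_km2, 0.001)
  expect_equal(sum(ls$n_cells), cfg$spec$nrow * cfg$spec$ncol)
  expect_true(all(ls$gradient_class %in% forest_gradient_classes()))
  expect_true(all(ls$area_km2 > 0))
})

test_that("a 4-polygon tiling of a 10x10 grid accounts for every cell", {
  cfg <- gen_config(grid_nrow = 10, grid_ncol = 10)
  ls <- gen_landscapes(cfg, n_tiles_x = 2, n_tiles_y = 2)
  expect_equal(nrow(ls), 4)
  expect_equal(sum(ls$n_cells), 100)
  # enumerate cells per polygon via cell centres
  cc <- cell_centres(cfg$spec)
  X <- matrix(cc$x, 10, 10, byrow = TRUE)
  Y <- matrix(cc$y, 10, 10)
  counted <- sapply(seq_len(4), function(i)
    sum(X >= ls$xmin[i] & X < ls$xmax[i] & Y >= ls$ymin[i] & Y < ls$ymax[i]))
  expect_equal(counted, ls$n_cells)
})

test_that("landscape requests beyond the grid are rejected", {
  cfg <- gen_config(grid_nrow = 4, grid_ncol = 4)
  expect_error(gen_landscapes(cfg, n_tiles_x = 5, n_tiles_y = 5), "tiles|cells")
})
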