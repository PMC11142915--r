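# Shared fixtures: small grids and hand-built point tables.

tiny_config <- function(seed = 1, n_points = 2000, ...) {
  gen_config(grid_nrow = 20, grid_ncol = 20, n_points = n_points, seed = seed,
             gcm_list = c("GCM-A", "GCM-B"), ...)
}

# every quality predicate passes
all_pass_fractions <- function() {
  list(weak_beam = 0, snow = 0, cloud = 0, solar = 0, rh98_range = 0,
       height_diff = 0, geoloc = 0)
}

# one-row-per-argument point table with passing defaults
make_points <- function(n = 1, rh98 = 10, beam = "strong", snow_flag = FALSE,
                        cloud_flag = FALSE, solar_elevation = 0,
                        landcover_class = "woodland", height_diff_ref = 5,
                        geoloc_error = 1, height_flagged = FALSE,
                        lon = 500, lat = 500) {
  data.frame(lon = rep_len(lon, n), lat = rep_len(lat, n),
             rh98 = rep_len(rh98, n), beam = rep_len(beam, n),
             snow_flag = rep_len(snow_flag, n),
             cloud_flag = rep_len(cloud_flag, n),
             solar_elevation = rep_len(solar_elevation, n),
             landcover_class = rep_len(landcover_class, n),
             height_diff_ref = rep_len(height_diff_ref, n),
             geoloc_error = rep_len(geoloc_error, n),
             height_flagged = rep_len(height_flagged, n),
             stringsAsFactors = FALSE)
}

# training table with response = true height law + gaussian noise,
# bypassing the lidar stage (used for model recovery checks)
law_response_table <- function(seed, nrow_grid = 40, ncol_grid = 40,
                               noise_sd = 0.5) {
  cfg <- gen_config(grid_nrow = nrow_grid, grid_ncol = ncol_grid, seed = seed)
  st <- gen_covariate_stacks(cfg)
  resp <- st$true_height
  set.seed(seed + 1000)
  if (noise_sd > 0)
    resp$values <- resp$values + rnorm(length(resp$values), sd = noise_sd)
  list(table = build_training_table(resp, st$current), stacks = st, config = cfg)
}
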