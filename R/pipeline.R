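#' Run the full structure-change assessment on a synthetic study system
#'
#' End-to-end composition of every stage: generate covariate stacks, lidar
#' points, the annual tree-canopy-cover series and the landscape tiling;
#' filter, flag, cap and grid the points; build the 22-predictor training
#' table, split 80/20, fit the 100-tree random forest and evaluate it;
#' predict current height and the 16 scenario ensembles; estimate per-pixel
#' TCC trends; summarise everything to landscape medians; and cross-
#' tabulate recent-by-future directions into the 9-class change taxonomy
#' for the chosen scenario.
#'
#' @param config A [gen_config()].
#' @param stable_band_height Stable band for median height difference (m).
#' @param stable_band_slope Stable band for median TCC slope (%/yr).
#' @param matrix_ssp,matrix_period Scenario used for the 9-class table
#'   (defaults: the second-severity SSP, i.e. a middle-of-the-road
#'   narrative, and the last 20-year period, reaching 2100).
#' @param n_tiles_x,n_tiles_y Landscape tiling, see [gen_landscapes()].
#' @param split_seed,model_seed Seeds of the train/test split and the
#'   forest.
#' @return List with components `stacks`, `points`, `gridded`, `table`,
#'   `split`, `fit`, `metrics`, `importance`, `current_prediction`,
#'   `differences` (16 difference maps), `tcc`, `trend`, `landscapes`
#'   (with medians and directions), `change_table`, `gradient_summary`.
#' @export
run_change_assessment <- function(config = gen_config(),
                                  stable_band_height = 0.5,
                                  stable_band_slope = 0.05,
                                  matrix_ssp = config$ssp_list[2],
                                  matrix_period = config$period_list[4],
                                  n_tiles_x = 5, n_tiles_y = 6,
                                  split_seed = config$seed,
                                  model_seed = config$seed) {
  stacks <- gen_covariate_stacks(config)
  pts <- gen_canopy_points(config, stacks$current)
  prep <- prepare_height_grid(pts$points, config$spec)

  tab <- build_training_table(prep$gridded$grid, stacks$current)
  split <- split_train_test(tab, 0.8, seed = split_seed)
  fit <- fit_height_model(split$train, n_trees = 100, seed = model_seed)
  metrics <- evaluate_model(fit, split$test)
  importance <- permutation_importance(fit, split$test, seed = model_seed)

  current_prediction <- predict_height_map(fit, stacks$current)
  differences <- run_all_scenarios(
    fit, stacks$future, current_prediction,
    keys = scenario_keys(config$ssp_list, config$period_list))

  tcc <- gen_tcc_series(config)
  trend <- trend_map(tcc)

  landscapes <- gen_landscapes(config, n_tiles_x, n_tiles_y)
  zs <- zonal_median(trend$slope, landscapes)
  landscapes$median_tcc_slope <- zs$median
  landscapes$median_tcc_p <- zonal_median(trend$p_value, landscapes)$median
  landscapes$recent_direction <-
    classify_direction(landscapes$median_tcc_slope, stable_band_slope)

  height_medians <- lapply(differences, function(d)
    zonal_median(d$grid, landscapes)$median)
  key <- paste(matrix_ssp, matrix_period, sep = "|")
  if (!key %in% names(height_medians))
    stop("scenario key ", key, " is not among the 16 difference maps")
  landscapes$median_height_diff <- height_medians[[key]]
  landscapes$future_direction <-
    classify_direction(landscapes$median_height_diff, stable_band_height)

  change_table <- change_matrix(landscapes)

  long <- do.call(rbind, lapply(names(height_medians), function(k)
    data.frame(gradient_class = landscapes$gradient_class, key = k,
               value = height_medians[[k]], stringsAsFactors = FALSE)))
  gradient_summary <- summarize_by_gradient_class(long)

  list(stacks = stacks, points = pts, gridded = prep$gridded,
       filtered = prep$filtered, table = tab, split = split, fit = fit,
       metrics = metrics, importance = importance,
       current_prediction = current_prediction, differences = differences,
       tcc = tcc, trend = trend, landscapes = landscapes,
       height_medians = height_medians,
       change_table = change_table, gradient_summary = gradient_summary,
       config = config,
       bands = list(height = stable_band_height, slope = stable_band_slope),
       matrix_key = key)
}
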