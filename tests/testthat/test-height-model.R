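test_that("training table links occupied cells to all 22 covariates", {
  cfg <- gen_config(grid_nrow = 5, grid_ncol = 5)
  st <- gen_covariate_stacks(cfg)
  vals <- matrix(NA_real_, 5, 5)
  vals[cbind(c(1, 2, 3, 4, 5), c(1, 3, 5, 2, 4))] <- c(4, 8, 12, 6, 10)
  tab <- build_training_table(raster_grid(vals, cfg$spec), st$current)
  expect_equal(nrow(tab), 5)
  expect_equal(ncol(tab), 2 + 22 + 1)  # cell indices + predictors + height
  expect_identical(attr(tab, "predictors"), predictor_names())
  # row values equal an independent per-cell lookup
  for (i in seq_len(nrow(tab))) {
    r <- tab$cell_row[i]; c <- tab$cell_col[i]
    for (p in predictor_names())
      expect_equal(tab[[p]][i], unname(st$current$values[r, c, p]))
    expect_equal(tab$height[i], vals[r, c])
  }
})

test_that("rows with missing covariates are dropped and counted", {
  cfg <- gen_config(grid_nrow = 5, grid_ncol = 5)
  st <- gen_covariate_stacks(cfg)
  st$current$values[1, 1, "permafrost_probability"] <- NA
  vals <- matrix(NA_real_, 5, 5)
  vals[cbind(1:5, 1:5)] <- 5
  tab <- build_training_table(raster_grid(vals, cfg$spec), st$current)
  expect_equal(nrow(tab), 4)
  expect_equal(attr(tab, "n_dropped"), 1)
})

test_that("misaligned grid and stack is a hard error", {
  cfg <- gen_config(grid_nrow = 5, grid_ncol = 5)
  st <- gen_covariate_stacks(cfg)
  other <- raster_grid(matrix(1, 6, 5), grid_spec(6, 5, cellsize = cfg$cellsize))
  expect_error(build_training_table(other, st$current), "co-registered")
})

test_that("the train/test split is exact, disjoint, exhaustive, reproducible", {
  tab <- data.frame(x = rnorm(1000), height = rnorm(1000))
  sp <- split_train_test(tab, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 800)
  expect_equal(nrow(sp$test), 200)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:1000)
  sp2 <- split_train_test(tab, 0.8, seed = 3)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_error(split_train_test(tab, 1.2), "fraction")
})

test_that("a constant response warns and predicts the constant", {
  tab <- data.frame(a = rnorm(50), b = rnorm(50), height = 8)
  expect_warning(fit <- fit_height_model(tab, n_trees = 20, seed = 1),
                 "constant")
  pred <- predict(fit$model, tab[, c("a", "b")], num.threads = 1)$predictions
  expect_true(all(pred == 8))
})

test_that("evaluation metrics equal an independent recomputation", {
  lr <- law_response_table(seed = 2, nrow_grid = 25, ncol_grid = 25)
  sp <- split_train_test(lr$table, 0.8, seed = 2)
  fit <- fit_height_model(sp$train, n_trees = 50, seed = 2)
  ev <- evaluate_model(fit, sp$test)
  pred <- predict(fit$model, sp$test[, fit$predictors], num.threads = 1)$predictions
  err <- pred - sp$test$height
  expect_equal(ev$bias, mean(err))
  expect_equal(ev$r2, 1 - sum(err^2) / sum((sp$test$height - mean(sp$test$height))^2))
  expect_equal(ev$bias_p, t.test(err)$p.value)
  expect_equal(ev$rmse, sqrt(mean(err^2)))
})

test_that("a constant-reference test set has undefined R2 and a clean bias", {
  tab <- data.frame(a = rnorm(100), height = 8)
  suppressWarnings(fit <- fit_height_model(tab, n_trees = 20, seed = 1))
  ev8 <- evaluate_model(fit, data.frame(a = rnorm(20), height = 8))
  expect_true(is.na(ev8$r2))  # SST = 0
  expect_equal(ev8$bias, 0)
  # shifting the reference down 2 m shifts the bias up 2 m
  ev6 <- evaluate_model(fit, data.frame(a = rnorm(20), height = 6))
  expect_equal(ev6$bias, 2)
})

test_that("permutation importance ranks the causal driver first and nulls last", {
  set.seed(9)
  n <- 1500
  tab <- data.frame(temperature = runif(n, -10, 5),
                    precipitation = runif(n, 100, 400),
                    null_predictor = rnorm(n))
  tab$height <- 15 * plogis(0.5 * (tab$temperature + 2)) +
    0.004 * tab$precipitation + rnorm(n, sd = 0.3)
  sp <- split_train_test(tab, 0.8, seed = 9)
  fit <- fit_height_model(sp$train, n_trees = 100, seed = 9)
  imp <- permutation_importance(fit, sp$test, n_repeats = 10, seed = 9)
  expect_equal(imp$predictor[1], "temperature")
  null_row <- imp[imp$predictor == "null_predictor", ]
  expect_lt(abs(null_row$importance), 3 * null_row$sd + 1e-8)
  # deterministic under the seed
  imp2 <- permutation_importance(fit, sp$test, n_repeats = 10, seed = 9)
  expect_identical(imp, imp2)
  expect_error(permutation_importance(fit, sp$test, n_repeats = 0), "n_repeats")
})

test_that("annual mean temperature dominates on the synthetic height law", {
  lr <- law_response_table(seed = 4, nrow_grid = 40, ncol_grid = 40,
                           noise_sd = 0.5)
  sp <- split_train_test(lr$table, 0.8, seed = 4)
  fit <- fit_height_model(sp$train, n_trees = 100, seed = 4)
  imp <- permutation_importance(fit, sp$test, seed = 4)
  expect_equal(imp$predictor[1], "bio01_annual_mean_temperature")
  # independent route: ranger's own out-of-bag permutation importance
  # agrees on the dominant predictor
  rf <- ranger::ranger(x = sp$train[, fit$predictors], y = sp$train$height,
                       num.trees = 100, seed = 4, num.threads = 1,
                       importance = "permutation")
  expect_equal(names(which.max(rf$variable.importance)),
               "bio01_annual_mean_temperature")
})

test_that("the height map equals row-wise predictions and propagates nodata", {
  lr <- law_response_table(seed = 6, nrow_grid = 20, ncol_grid = 20)
  sp <- split_train_test(lr$table, 0.8, seed = 6)
  fit <- fit_height_model(sp$train, n_trees = 50, seed = 6)
  st <- lr$stacks$current
  st$values[3, 7, "bio12_annual_precipitation"] <- NA  # one nodata pixel
  map <- predict_height_map(fit, st)
  expect_true(is.na(map$values[3, 7]))
  set.seed(6)
  cells <- cbind(sample(20, 50, replace = TRUE), sample(20, 50, replace = TRUE))
  cells <- cells[!(cells[, 1] == 3 & cells[, 2] == 7), , drop = FALSE]
  tab <- as.data.frame(t(apply(cells, 1, function(rc)
    st$values[rc[1], rc[2], fit$predictors])))
  names(tab) <- fit$predictors
  pred <- predict(fit$model, tab, num.threads = 1)$predictions
  expect_equal(map$values[cells], pred)
})

test_that("a predictor-name mismatch is an error listing the names", {
  lr <- law_response_table(seed = 6, nrow_grid = 20, ncol_grid = 20)
  sp <- split_train_test(lr$table, 0.8, seed = 6)
  fit <- fit_height_model(sp$train, n_trees = 20, seed = 6)
  st <- lr$stacks$current
  st$values <- st$values[, , -1]
  st$layers <- st$layers[-1]
  expect_error(predict_height_map(fit, st), "permafrost_probability")
})

test_that("predictions are less dispersed than the reference heights", {
  # the model smooths extremes: predicted variance <= reference variance
  lr <- law_response_table(seed = 10, nrow_grid = 30, ncol_grid = 30,
                           noise_sd = 1)
  sp <- split_train_test(lr$table, 0.8, seed = 10)
  fit <- fit_height_model(sp$train, n_trees = 100, seed = 10)
  pred <- predict(fit$model, sp$test[, fit$predictors], num.threads = 1)$predictions
  expect_lte(var(pred), var(sp$test$height))
})
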