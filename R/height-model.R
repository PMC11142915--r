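#' Build the 22-predictor training table
#'
#' Links every occupied (non-nodata) cell of the gridded canopy-height
#' response to the 22 covariate values of the co-registered stack. Rows
#' with any missing covariate are dropped and counted.
#'
#' @param grid A [raster_grid()] of gridded canopy height (m).
#' @param stack The current covariate [raster_stack()] with the 22
#'   predictors; must share the grid's geometry (resampling, if needed, is
#'   the caller's responsibility and declared choice).
#' @return Data frame with columns `cell_row`, `cell_col`, the 22
#'   predictors, and `height`; attribute `n_dropped` counts rows lost to
#'   missing covariates, attribute `predictors` names the predictor columns.
#' @export
build_training_table <- function(grid, stack) {
  stop_if_misaligned(grid$spec, stack$spec, "height grid and covariate stack")
  missing_layers <- setdiff(predictor_names(), stack$layers)
  if (length(missing_layers))
    stop("covariate stack is missing predictor layer(s): ",
         paste(missing_layers, collapse = ", "))
  occ <- which(!is.na(grid$values), arr.ind = TRUE)
  preds <- predictor_names()
  tab <- matrix(NA_real_, nrow(occ), length(preds), dimnames = list(NULL, preds))
  for (j in seq_along(preds)) {
    lay <- stack$values[, , preds[j]]
    tab[, j] <- lay[occ]
  }
  out <- data.frame(cell_row = occ[, 1], cell_col = occ[, 2], tab,
                    height = grid$values[occ], check.names = FALSE)
  complete <- stats::complete.cases(out[, preds, drop = FALSE])
  dropped <- sum(!complete)
  out <- out[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  attr(out, "predictors") <- preds
  out
}

#' Split a training table into train and test sets
#'
#' Uniform random split without replacement, reproducible under the seed.
#'
#' @param table A training table from [build_training_table()].
#' @param fraction Training fraction, in (0, 1); default 0.8 (an 80/20
#'   split).
#' @param seed Integer seed for the split.
#' @return List with `train`, `test`, `train_idx`, `test_idx`.
#' @export
split_train_test <- function(table, fraction = 0.8, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(table)
  if (n < 10) stop("need at least 10 rows to split")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  train_idx <- sort(sample.int(n, round(fraction * n)))
  test_idx <- setdiff(seq_len(n), train_idx)
  train <- table[train_idx, , drop = FALSE]
  test <- table[test_idx, , drop = FALSE]
  attr(train, "predictors") <- attr(table, "predictors")
  attr(test, "predictors") <- attr(table, "predictors")
  list(train = train, test = test,
       train_idx = train_idx, test_idx = test_idx)
}

#' Fit the random-forest canopy height model
#'
#' Random-forest regression of gridded canopy height on the 22 predictors,
#' limited to 100 trees by default (only the tree count is pinned; the
#' remaining hyperparameters are the library defaults, exposed via `...`).
#' Fitting is single-threaded and seeded for reproducibility.
#'
#' @param train Training rows (from [split_train_test()]).
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed for tree growing.
#' @param predictors Predictor column names; defaults to the table's
#'   `predictors` attribute, or every column except `cell_row`, `cell_col`
#'   and `height`.
#' @param ... Passed on to [ranger::ranger()] (e.g. `mtry`,
#'   `min.node.size`, `max.depth`).
#' @return An object of class `height_model_fit`: the fitted forest, the
#'   predictor names, the in-sample training R-squared and the seed.
#' @export
fit_height_model <- function(train, n_trees = 100, seed = 1,
                             predictors = NULL, ...) {
  if (nrow(train) == 0) stop("training table is empty")
  preds <- predictors
  if (is.null(preds)) preds <- attr(train, "predictors")
  if (is.null(preds))
    preds <- setdiff(names(train), c("cell_row", "cell_col", "height"))
  if (stats::var(train$height) == 0)
    warning("response is constant; the fit will predict a constant")
  rf <- ranger::ranger(
    x = train[, preds, drop = FALSE], y = train$height,
    num.trees = n_trees, seed = seed, num.threads = 1, ...)
  pred_train <- stats::predict(rf, train[, preds, drop = FALSE],
                               num.threads = 1)$predictions
  sst <- sum((train$height - mean(train$height))^2)
  r2_train <- if (sst > 0) 1 - sum((train$height - pred_train)^2) / sst else NA_real_
  structure(list(model = rf, predictors = preds, n_trees = n_trees,
                 seed = seed, r2_train = r2_train,
                 r2_oob = rf$r.squared, n_train = nrow(train)),
            class = "height_model_fit")
}

#' @export
print.height_model_fit <- function(x, ...) {
  cat(sprintf("<height_model_fit> %d trees, %d predictors, n = %d, train R2 = %.3f (OOB %.3f)\n",
              x$n_trees, length(x$predictors), x$n_train, x$r2_train, x$r2_oob))
  invisible(x)
}

# predictions for rows of a table carrying the fit's predictors
predict_rows <- function(fit, data) {
  stats::predict(fit$model, data[, fit$predictors, drop = FALSE],
                 num.threads = 1)$predictions
}

#' Evaluate a fitted height model on held-out rows
#'
#' Computes test R-squared (`1 - SSE/SST` against the reference heights),
#' the bias `mean(predicted - reference)` in metres, and a two-sided
#' one-sample t-test of zero mean on the prediction errors for the bias
#' p-value.
#'
#' @param fit A [fit_height_model()] result.
#' @param test Held-out rows with the predictors and `height`.
#' @return List with `r2` (NA when the reference variance is zero), `bias`,
#'   `bias_p`, `rmse`, `n`.
#' @export
evaluate_model <- function(fit, test) {
  if (nrow(test) == 0) stop("test table is empty")
  pred <- predict_rows(fit, test)
  err <- pred - test$height
  sst <- sum((test$height - mean(test$height))^2)
  r2 <- if (sst > 0) 1 - sum(err^2) / sst else NA_real_
  bias_p <- if (length(err) > 1 && stats::sd(err) > 0)
    stats::t.test(err)$p.value else NA_real_
  list(r2 = r2, bias = mean(err), bias_p = bias_p,
       rmse = sqrt(mean(err^2)), n = nrow(test))
}

#' Permutation importance of the height predictors
#'
#' For each predictor, permutes its column `n_repeats` times on the
#' evaluation data and records the mean increase in prediction mean squared
#' error over the unpermuted baseline. Predictors are returned in
#' descending importance; ties break alphabetically by predictor name.
#'
#' @param fit A [fit_height_model()] result.
#' @param data Evaluation rows with the predictors and `height` (typically
#'   the held-out set).
#' @param n_repeats Number of permutations per predictor (default 10).
#' @param seed Integer seed for the permutations.
#' @return Data frame with `predictor`, `importance` (mean MSE increase),
#'   `sd` (across repeats) and `rank`.
#' @export
permutation_importance <- function(fit, data, n_repeats = 10, seed = 1) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  base_mse <- mean((predict_rows(fit, data) - data$height)^2)
  n <- nrow(data)
  imp <- sd_ <- numeric(length(fit$predictors))
  for (j in seq_along(fit$predictors)) {
    p <- fit$predictors[j]
    delta <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      shuffled <- data
      shuffled[[p]] <- shuffled[[p]][sample.int(n)]
      delta[r] <- mean((predict_rows(fit, shuffled) - data$height)^2) - base_mse
    }
    imp[j] <- mean(delta)
    sd_[j] <- stats::sd(delta)
  }
  ord <- order(-imp, fit$predictors)
  out <- data.frame(predictor = fit$predictors[ord], importance = imp[ord],
                    sd = sd_[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Predict a canopy-height map from a covariate stack
#'
#' Applies the fitted model pixel-wise; pixels with any missing predictor
#' are nodata. The stack must carry exactly the fit's predictors (extra
#' layers beyond them are an error, as is any missing one).
#'
#' @param fit A [fit_height_model()] result.
#' @param stack A covariate [raster_stack()].
#' @return A [raster_grid()] of predicted height (m).
#' @export
predict_height_map <- function(fit, stack) {
  missing_layers <- setdiff(fit$predictors, stack$layers)
  extra <- setdiff(stack$layers, fit$predictors)
  if (length(missing_layers) || length(extra))
    stop("predictor mismatch; missing: [",
         paste(missing_layers, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  nr <- stack$spec$nrow; nc <- stack$spec$ncol
  tab <- matrix(NA_real_, nr * nc, length(fit$predictors),
                dimnames = list(NULL, fit$predictors))
  for (j in seq_along(fit$predictors))
    tab[, j] <- as.vector(stack$values[, , fit$predictors[j]])
  ok <- stats::complete.cases(tab)
  out <- rep(NA_real_, nr * nc)
  if (any(ok))
    out[ok] <- predict_rows(fit, as.data.frame(tab[ok, , drop = FALSE]))
  raster_grid(matrix(out, nr, nc), stack$spec,
              name = paste0("predicted_height_", stack$period))
}
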