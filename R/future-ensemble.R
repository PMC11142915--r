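#' The 16 scenario keys (4 SSPs x 4 periods)
#'
#' @param ssp_list 4 SSP labels ordered by severity.
#' @param period_list 4 period labels ordered in time.
#' @return Data frame with `ssp`, `period`, `ssp_rank`, `period_index`,
#'   `key` (`"ssp|period"`), 16 rows.
#' @export
scenario_keys <- function(ssp_list = gen_config()$ssp_list,
                          period_list = gen_config()$period_list) {
  if (length(ssp_list) != 4L || length(period_list) != 4L)
    stop("expected 4 SSPs and 4 periods")
  g <- expand.grid(period_index = seq_along(period_list),
                   ssp_rank = seq_along(ssp_list))
  data.frame(ssp = ssp_list[g$ssp_rank], period = period_list[g$period_index],
             ssp_rank = g$ssp_rank, period_index = g$period_index,
             key = paste(ssp_list[g$ssp_rank], period_list[g$period_index],
                         sep = "|"),
             stringsAsFactors = FALSE)
}

#' Predict potential canopy height for every GCM-scenario stack
#'
#' Applies the fitted height model to each future covariate stack,
#' producing one prediction raster per (GCM, SSP, period) present in the
#' input. Missing GCM-scenario combinations are tolerated: the ensemble for
#' a key simply uses the GCMs that are available.
#'
#' @param fit A [fit_height_model()] result.
#' @param stacks Named list of future [raster_stack()]s (as produced by
#'   [gen_covariate_stacks()]`$future`).
#' @return Named list of [raster_grid()] predictions keyed
#'   `"gcm|ssp|period"`; each element carries `ssp`, `period`, `gcm`
#'   attributes.
#' @export
predict_all_gcms <- function(fit, stacks) {
  if (length(stacks) == 0) stop("no covariate stacks supplied")
  out <- vector("list", length(stacks))
  names(out) <- names(stacks)
  for (k in names(stacks)) {
    s <- stacks[[k]]
    g <- predict_height_map(fit, s)
    attr(g, "ssp") <- s$ssp
    attr(g, "period") <- s$period
    attr(g, "gcm") <- s$gcm
    out[[k]] <- g
  }
  out
}

#' Pixel-wise ensemble median over GCM predictions
#'
#' Reduces the predictions of the available GCMs for one (SSP, period) to a
#' single consensus map: the per-pixel median, ignoring nodata entries, so
#' a pixel is nodata only where every GCM is nodata. With an even number of
#' values the median is the mean of the two central values. The per-pixel
#' count of contributing GCMs is returned for auditability.
#'
#' @param predictions List of co-registered [raster_grid()]s, one per GCM.
#' @return List with `grid` (the median [raster_grid()]) and `n_used` (a
#'   [raster_grid()] of per-pixel GCM counts).
#' @export
ensemble_median <- function(predictions) {
  if (length(predictions) == 0) stop("no predictions supplied")
  spec <- predictions[[1]]$spec
  for (p in predictions) stop_if_misaligned(spec, p$spec, "GCM predictions")
  arr <- vapply(predictions, function(p) p$values,
                matrix(0, spec$nrow, spec$ncol))
  dim(arr) <- c(spec$nrow * spec$ncol, length(predictions))
  med <- apply(arr, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) stats::median(v) else NA_real_
  })
  n_used <- rowSums(!is.na(arr))
  list(grid = raster_grid(matrix(med, spec$nrow, spec$ncol), spec,
                          name = "ensemble_median"),
       n_used = raster_grid(matrix(n_used, spec$nrow, spec$ncol), spec,
                            name = "n_gcms"))
}

#' Difference a future ensemble median from the current prediction
#'
#' `future - current` per pixel. Differencing against the same model's
#' current prediction normalises the future maps and mitigates biases
#' inherent in the model-based heights. Nodata wherever either operand is
#' nodata.
#'
#' @param future_median Ensemble-median [raster_grid()] for one scenario.
#' @param current_prediction Current predicted-height [raster_grid()].
#' @param key Optional scenario key recorded on the result.
#' @return An object of class `difference_map`: list with `grid`, `key`,
#'   `ssp`, `period`.
#' @export
difference_from_current <- function(future_median, current_prediction,
                                    key = NULL) {
  stop_if_misaligned(future_median$spec, current_prediction$spec,
                     "future and current predictions")
  d <- future_median$values - current_prediction$values
  structure(list(grid = raster_grid(d, future_median$spec,
                                    name = "height_difference"),
                 key = key,
                 ssp = attr(future_median, "ssp"),
                 period = attr(future_median, "period")),
            class = "difference_map")
}

#' Run the full scenario ensemble: 16 difference maps
#'
#' For each of the 16 (SSP, period) keys, pools the available GCM
#' predictions, takes the pixel-wise ensemble median, and subtracts the
#' current prediction. A key with no GCM prediction at all is a hard error
#' naming the key.
#'
#' @param fit A [fit_height_model()] result.
#' @param stacks Named list of future covariate stacks (one per GCM x SSP x
#'   period available).
#' @param current_prediction Current predicted-height [raster_grid()].
#' @param keys Scenario key table from [scenario_keys()]; defaults to the
#'   keys present in `stacks`.
#' @return Named list of 16 `difference_map` objects keyed
#'   `"ssp|period"`; each carries `n_gcms`, the number of GCMs pooled.
#' @export
run_all_scenarios <- function(fit, stacks, current_prediction, keys = NULL) {
  preds <- predict_all_gcms(fit, stacks)
  tags <- data.frame(
    ssp = vapply(stacks, function(s) s$ssp, ""),
    period = vapply(stacks, function(s) s$period, ""),
    stringsAsFactors = FALSE)
  if (is.null(keys)) {
    u <- unique(tags)
    keys <- data.frame(ssp = u$ssp, period = u$period,
                       key = paste(u$ssp, u$period, sep = "|"),
                       stringsAsFactors = FALSE)
  }
  out <- vector("list", nrow(keys))
  names(out) <- keys$key
  for (i in seq_len(nrow(keys))) {
    sel <- tags$ssp == keys$ssp[i] & tags$period == keys$period[i]
    if (!any(sel))
      stop("no GCM predictions available for scenario key ", keys$key[i])
    em <- ensemble_median(preds[sel])
    attr(em$grid, "ssp") <- keys$ssp[i]
    attr(em$grid, "period") <- keys$period[i]
    dm <- difference_from_current(em$grid, current_prediction,
                                  key = keys$key[i])
    dm$n_gcms <- sum(sel)
    dm$n_used <- em$n_used
    out[[i]] <- dm
  }
  out
}
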