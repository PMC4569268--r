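#' Compare observed and predicted response vectors
#'
#' Computes the standard agreement statistics between paired observed and
#' predicted activities: root-mean-square error, mean absolute percentage
#' error, the coefficient of determination `1 - SSE/SST`, and the Pearson
#' correlation. Alongside the standard RMSE the report carries
#' `rmse_x10 = 10 * rmse`: the bundled dataset's source summarized its
#' model comparison with RMSE values on exactly this ten-fold scale, so
#' both are reported to keep comparisons unambiguous.
#'
#' @param observed,predicted Equal-length numeric vectors (U/mL).
#' @return Object of class `comparison_report`: `n`, `rmse`, `rmse_x10`,
#'   `mape_percent`, `r_squared`, `r`. `mape_percent` is `NA` (with a
#'   warning) when any observed value is zero.
#' @export
model_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (!length(observed)) stop("empty vectors", call. = FALSE)
  err <- observed - predicted
  rmse <- sqrt(mean(err^2))
  if (any(observed == 0)) {
    warning("MAPE undefined with zero observed values; reporting NA")
    mape <- NA_real_
  } else {
    mape <- 100 * mean(abs(err) / abs(observed))
  }
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst > 0) 1 - sum(err^2) / sst else NA_real_
  structure(
    list(n = length(observed), rmse = rmse, rmse_x10 = 10 * rmse,
         mape_percent = mape, r_squared = r2,
         r = suppressWarnings(stats::cor(observed, predicted))),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "<comparison_report> n = %d | RMSE %.4f (x10: %.3f) | MAPE %s%% | R^2 %s\n",
    x$n, x$rmse, x$rmse_x10,
    ifelse(is.na(x$mape_percent), "NA", sprintf("%.2f", x$mape_percent)),
    ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  invisible(x)
}

#' Fold change of an optimized titre over a baseline
#'
#' @param optimized Activity after optimization (U/mL).
#' @param baseline Activity of the unoptimized reference medium (U/mL),
#'   must be positive.
#' @return `optimized / baseline`.
#' @export
fold_change <- function(optimized, baseline) {
  if (!is.finite(baseline) || baseline <= 0) {
    stop("baseline must be a positive activity", call. = FALSE)
  }
  optimized / baseline
}
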